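# SYNTHETIC placeholder bounds for `omgrowth classify` / classifyConsistent().
#
# The experimental acceptance levels for the initial punctum appearance rate
# and the maximum puncta count (both per um of cell outline perimeter) are
# determined graphically from experiment and are not shipped as truth by this
# package: edit these intervals to your own measured levels before
# classifying a scan. The numbers below are illustrative values on the scale
# produced by the default simulation + detection pipeline.
rate:        # puncta per s per um of perimeter
  - 2.0e-4
  - 8.0e-4
max_count:   # puncta per um of perimeter
  - 0.3
  - 0.8
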