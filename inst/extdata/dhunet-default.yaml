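depth: 4
base_filters: 8
filter_growth: 2
kernel_size: 3
use_batchnorm: yes
upsample_mode: interp
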