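"specimen","layer","P","Ca","Mg"
"HELIX","outer",13.5,20.9,0.1
"HELIX","outer",13.7,21,0.2
"HELIX","outer",13.6,21.1,0.3
"control","outer",13.5,21.4,0.1
"control","outer",13.7,21.6,0.2
"control","outer",13.6,21.5,0.3
"HELIX","inner",12.7,20.2,0.4
"HELIX","inner",13.6,21.4,0.5
"HELIX","inner",12.7,20.5,0.3
"control","inner",13.8,22.1,0.4
"control","inner",14,22.4,0.4
"control","inner",13.9,22.1,0.4
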