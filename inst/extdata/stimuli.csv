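name,theta_BC,theta_CA,theta_AB,description
beck_gibson_1,5.538,5.538,6.573,Beck & Gibson (1955) Experiment 1 triangle orientation 1
beck_gibson_2,4.928,4.928,6.638,Beck & Gibson (1955) Experiment 1 triangle orientation 2
beck_gibson_3,4.222,4.222,6.689,Beck & Gibson (1955) Experiment 1 triangle orientation 3
watanabe_left,41.19,27.68,31.01,Watanabe (2004) Condition 3 left-eye image
watanabe_right,41.18,27.78,30.91,Watanabe (2004) Condition 3 right-eye image
fig3_text_small,9,10,11,small-image example as analyzed in the running text
fig3_caption_small,10,15,20,small-image example as stated in the figure caption
fig3_large,90,100,110,large-image example
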