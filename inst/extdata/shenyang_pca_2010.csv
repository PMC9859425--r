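component,eigenvalue,contribution_rate,cumulative_contribution_rate
PC1,3.143,24.175,24.175
PC2,1.919,14.763,38.939
PC3,1.866,14.351,53.290
PC4,1.780,13.690,66.980
PC5,1.707,13.129,80.109
PC6,1.053,8.099,88.207
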