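class,slight,light,medium,heavy,extreme
slight,2605.072,14.495,1.926,—,—
light,1045.461,4699.673,53.467,—,—
medium,—,891.258,2265.241,3.081,—
heavy,—,—,218.713,692.655,20.075
extreme,—,—,—,1.266,350.163
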