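sample_id	label	host
sample_1	c1	h1
sample_2	c1	h1
sample_3	c1	h2
sample_4	c1	h2
sample_5	c1	h3
sample_6	c1	h3
sample_7	c1	h4
sample_8	c1	h4
sample_9	c1	h5
sample_10	c1	h5
sample_11	c1	h6
sample_12	c1	h6
sample_13	c2	h7
sample_14	c2	h7
sample_15	c2	h8
sample_16	c2	h8
sample_17	c2	h9
sample_18	c2	h9
sample_19	c2	h10
sample_20	c2	h10
sample_21	c2	h11
sample_22	c2	h11
sample_23	c2	h12
sample_24	c2	h12
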