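sample_id	group
S01	healthy
S02	healthy
S03	healthy
S04	healthy
S05	healthy
S06	healthy
S07	healthy
S08	healthy
S09	disease
S10	disease
S11	disease
S12	disease
S13	disease
S14	disease
S15	disease
S16	disease
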