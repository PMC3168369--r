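build: reading interactions from /tmp/RtmpoNbisK/file6e9774427b8/absent.tsv (simple_tsv)
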