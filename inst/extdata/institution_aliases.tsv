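alias	canonical
MSKCC	Memorial Sloan Kettering
Memorial Sloan Kettering Cancer Center	Memorial Sloan Kettering
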