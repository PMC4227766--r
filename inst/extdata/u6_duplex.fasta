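>U6_probe_non_template 78 nt, PSEA (21 bp) at offset 31
GCTATGACCATGATTACGAATTCATTCTTATAATTCTCAACTGCTCTTTCCGGTACCGCCATGGAAAGGTATGGGATC
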