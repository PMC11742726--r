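>TruSeq_R1
AGATCGGAAGAGCACACGTCTGAACTCCAGTCA
>TruSeq_R2
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT
>Nextera_R1
CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
>Nextera_R2
CTGTCTCTTATACACATCTGACGCTGCCGACGA
>Illumina_SmallRNA_3p
TGGAATTCTCGGGTGCCAAGG
>Illumina_SmallRNA_5p
GATCGTCGGACTGTAGAACTCTGAAC
>Illumina_Universal
AGATCGGAAGAG
>PolyG
GGGGGGGGGGGGGGGG
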