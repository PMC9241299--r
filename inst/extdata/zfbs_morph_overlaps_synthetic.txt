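# SYNTHETIC stand-in catalog of ZFBS-morph overlaps (class ZFBS_MORPH).
#
# The published list of composite elements — ZFP57 hexamer overlapping a
# CpG-rich MLL morpheme — is not redistributed with this package. The
# entries below are illustrative composites built around the TGCCGC
# hexamer so that examples and the command line run out of the box; they
# are NOT the published set. For real analyses, transcribe the published
# composite sequences into a catalog file of this format and pass it with
# --morph-catalog / load_catalog().
ov1	TGCCGCGCA
ov2	CGCCTGCCGC
ov3	TGCCGCCCG
ov4	GCGCTGCCGC
ov5	TGCCGCGGC
ov6	CCGCTGCCGC
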