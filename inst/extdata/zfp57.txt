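# Default ZFP57 binding-site catalog (class ZFP57).
# The hexameric recognition site commonly reported for ZFP57; scanning is
# sequence-only (the methylated-CpG preference of ZFP57 is not modelled).
# Override with your own catalog file to use a different site set.
ZFP57	TGCCGC
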