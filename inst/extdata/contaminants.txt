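# Common TAP/MS contaminant classes, one glob pattern per line.
# Edit freely; categories become the filter_reason of flagged rows.

[heat_shock]
Hsp*
Hsc70*
DnaJ*

[ribosomal]
RpL*
RpS*
mRpL*
mRpS*
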