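# Published overall risk-of-bias ratings for 17 physiotherapy meta-analyses:
# consensus of a blinded external review panel versus the original Cochrane
# review authors, with the published agreement/disagreement partition.
# Note: the Puhan 2010 pair is listed under disagreements in the published
# partition although both printed ratings are "high"; values and partition
# are transcribed verbatim.
meta_analysis,external,cochrane,printed_section
Orozco 2008,unclear,unclear,agreement
Sirtory 2009,unclear,unclear,agreement
Davies 2010,unclear,unclear,agreement
States 2009,unclear,high,disagreement
Fransen 2009,high,low,disagreement
Handoll 2009,high,unclear,disagreement
Effing 2009,high,unclear,disagreement
Taylor 2010,unclear,high,disagreement
Harvey 2010,unclear,high,disagreement
Rutjes 2010,unclear,high,disagreement
Katalinic 2010,unclear,high,disagreement
Puhan 2010,high,high,disagreement
Kramer 2010,unclear,high,disagreement
Rutjes 2010b,unclear,high,disagreement
Manheimer 2010,unclear,high,disagreement
Ostelo 2011,unclear,high,disagreement
Schaafsma 2011,unclear,high,disagreement
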