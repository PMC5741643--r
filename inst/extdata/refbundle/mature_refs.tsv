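id	label	residues
kalata_B1	archetypal_moebius	GLPVCGETCVGGTCNTPGCTCSWPVCTRN
cycloviolacin_O2	archetypal_bracelet	GIPCGESCVWIPCISSAIGCSCKSKVCYRN
syn_YS1_m	hybrid	GLPACGQTCVGGTCNSPGCNCTWPVCARN
syn_YS2_m	hybrid	GLPICGQTCLGGACNSPGCSCTWPICSRN
syn_YS3_m	archetypal_moebius	GLPTCGQTCVGGACNTPGCNCTWPVCTRN
syn_YS4_m	archetypal_moebius	GLPACGETCLGGSCNTPGCTCSWPVCARN
syn_YY1_m	linear	GLPTCGETCVGGACNTPGCNCTWPICTRS
syn_YY2_m	linear	GLPICGDTCLGGACNSPGCNCTWPICSRS
syn_YA1_m	hybrid	GLPACGETCLGGSCNTPGCNCTWPICSRN
syn_YA2_m	archetypal_moebius	GLPICGQTCLGGTCNSPGCSCSWPICTRN
syn_HF1_m	hybrid	GLPTCGQTCLGGTCNTPGCSCTWPVCARN
syn_HF2_m	archetypal_moebius	GLPTCGETCLGGTCNSPGCTCTWPVCSRN
syn_FA1_m	hybrid	GLPACGQTCLGGACNTPGCTCTWPVCSRN
syn_FA2_m	archetypal_moebius	GLPICGETCVGGACNSPGCTCTWPICSRN
syn_FA3_m	archetypal_moebius	GLPICGQTCLGGSCNSPGCTCTWPICARN
syn_FA4_m	hybrid	GLPACGETCVGGSCNSPGCTCSWPICTRN
syn_HS1_m	archetypal_bracelet	GIPTCGDSCIWLPCVSSGIGCSCKTKCFRN
syn_HS2_m	archetypal_bracelet	GVPTCGESCIWIPCVSSGIGCTCKSKCFRN
syn_HS3_m	archetypal_bracelet	GVPVCGESCVWIPCISSAIGCTCKTKCYRN
syn_HS4_m	archetypal_bracelet	GVPVCGESCVWLPCVSSAIGCSCKSKCYRN
syn_HS5_m	archetypal_bracelet	GVPVCGESCIWIPCVSSGLGCSCKTKCYRN
syn_HS6_m	archetypal_bracelet	GIPTCGDSCIWLPCISSGIGCTCKTKCYRN
syn_NS1_m	archetypal_bracelet	GVPTCGESCIWLPCVSSAIGCTCKTKCFRN
syn_NS2_m	archetypal_bracelet	GVPVCGESCVWIPCISSALGCTCKTKCYRN
syn_NS3_m	archetypal_bracelet	GIPVCGESCVWLPCISSGLGCSCKSKCFRN
syn_NS4_m	archetypal_bracelet	GIPACGESCIWIPCVSSAIGCSCKSKCYRN
syn_NS5_m	archetypal_bracelet	GVPVCGESCVWLPCVSSGLGCTCKSKCFRN
syn_NL1_m	archetypal_bracelet	GIPVCGDSCIWLPCVSSALGCTCKSKCYRN
syn_NL2_m	archetypal_bracelet	GIPACGDSCIWLPCVSSGIGCSCKSKCFRN
syn_NL3_m	archetypal_bracelet	GVPVCGESCIWIPCISSGLGCTCKSKCFRN
syn_GA1_m	archetypal_bracelet	GVPACGESCIWLPCVSSGLGCTCKSKCFRN
syn_GA2_m	archetypal_bracelet	GIPVCGDSCIWLPCVSSGLGCSCKSKCFRN
syn_GA3_m	archetypal_bracelet	GIPACGDSCVWIPCISSGLGCTCKSKCFRN
syn_GP1_m	archetypal_bracelet	GVPACGDSCIWLPCISSGLGCSCKTKCYRN
syn_GP2_m	archetypal_bracelet	GVPTCGESCVWLPCISSAIGCSCKSKCYRN
syn_RS1_m	archetypal_bracelet	GVPACGESCIWLPCISSGIGCSCKTKCYRN
syn_RS2_m	archetypal_bracelet	GVPACGDSCVWLPCVSSAIGCTCKSKCFRN
syn_RS3_m	archetypal_bracelet	GIPTCGESCIWIPCISSGIGCSCKSKCFRN
syn_RS4_m	archetypal_bracelet	GIPACGESCIWLPCVSSGLGCTCKSKCYRN
syn_RS5_m	archetypal_bracelet	GVPVCGESCVWLPCISSAIGCSCKSKCFRN
syn_RS6_m	archetypal_bracelet	GVPTCGESCIWIPCVSSGLGCSCKSKCYRN
syn_PN1_m	linear	GIPACGESCVWIPCISSGIGCSCKSKCSKG
syn_PN2_m	linear	GIPVCGESCIWIPCVSSAIGCTCKTKCTKG
syn_PN3_m	linear	GIPVCGESCVWIPCISSAIGCSCKSKCTKS
syn_PN4_m	linear	GVPTCGESCIWLPCVSSALGCSCKTKCSKG
syn_QD1_m	linear	GIPTCGDSCVWIPCISSGLGCSCKTKCSKS
syn_QD2_m	linear	GVPACGESCIWIPCVSSGIGCTCKTKCTKG
syn_QD3_m	linear	GVPTCGDSCIWLPCVSSAIGCSCKTKCTKG
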