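context	note
QQPQQSF	core Q2 of PQQSFPQQQ-type epitopes
FPQQQQL	Q8 of QQQQ run after F, before L
SPQQQQL	Q8 of QQQQ run after S, before L
PQQQQLM	Q9 of QQQQ run before LM
PQQQQLL	Q9 of QQQQ run before LL
QQQQLMI	flank +1 Q before LMI
QQQQLLI	flank +1 Q before LLI
FPQQQQW	Q8 of QQQQ run before W
PQQQQWM	Q9 of QQQQ run before WM
QQQQWMI	flank +1 Q before WMI
PQQQRSF	Q9 before an arginine flank
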