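C0010951|ENG|P|L0010951|PF|S0033898|Y|A23511234|||HP:0000518|HPO|PT|HP:0000518|Cataract|0|N|256|
C0010951|ENG|S|L0010952|PF|S0033899|Y|A23511235|||HP:0000518|HPO|SY|HP:0000518|Cataracts|0|N|256|
C3277723|ENG|P|L3277723|PF|S0033900|Y|A23511236|||HP:0010920|HPO|PT|HP:0010920|Zonular cataract|0|N|256|
C4023906|ENG|P|L4023906|PF|S0033901|Y|A23511237|||HP:0000517|HPO|PT|HP:0000517|Abnormality of the lens|0|N|256|
C0015393|ENG|P|L0015393|PF|S0033902|Y|A23511238|||HP:0000478|HPO|PT|HP:0000478|Abnormality of the eye|0|N|256|
C1868508|ENG|P|L1868508|PF|S0033903|Y|A23511239|||123456789|SNOMEDCT_US|PT|123456789|Cataract of eye|0|N|256|
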