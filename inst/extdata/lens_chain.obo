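format-version: 1.2

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001 ! All

[Term]
id: HP:0000478
name: Abnormality of the eye
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0012372
name: Abnormal eye morphology
is_a: HP:0000478 ! Abnormality of the eye

[Term]
id: HP:0000517
name: Abnormality of the lens
is_a: HP:0012372 ! Abnormal eye morphology

[Term]
id: HP:0000518
name: Cataract
synonym: "Cataracts" EXACT []
synonym: "Lens opacity" EXACT []
is_a: HP:0000517 ! Abnormality of the lens

[Term]
id: HP:0010920
name: Zonular cataract
is_a: HP:0000518 ! Cataract
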