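#traitguilds-rules v1
rule_name	expression	substrate_class
denitrification_step1	(narG & narH & narI) | (napA & napB)	.
denitrification_step2	nirS | nirK	.
denitrification_step3	(norB & norC) | (norV & norW)	.
denitrification_step4	nosZ	.
denitrification_to_N2	denitrification_step1 & denitrification_step2 & denitrification_step3 & denitrification_step4	.
denitrification_to_N2_from_nitrite	!denitrification_step1 & denitrification_step2 & denitrification_step3 & denitrification_step4	.
denitrification_to_N2O	denitrification_step1 & denitrification_step2 & denitrification_step3 & !denitrification_step4	.
denitrification_any	denitrification_step1 | denitrification_step2 | denitrification_step3 | denitrification_step4	.
xylFGH_transporter	xylF & xylG & xylH	monosaccharides
malEFGK_transporter	malE & malF & malG & malK	disaccharides
chaperone_general	dnaK | groEL	.
oxidative_stress_defense	katE | sodA	.
trehalose_synthesis	otsA & otsB	.
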