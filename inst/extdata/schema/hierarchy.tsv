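#traitguilds-hierarchy v1
trait_name	level1	level2	level3	strategy	value_type	binding	substrate_class
denitrification_complete	Resource Use	Denitrification	NO3 to N2	resource use	binary	denitrification_to_N2	.
denitrification_from_nitrite	Resource Use	Denitrification	NO2 to N2	resource use	binary	denitrification_to_N2_from_nitrite	.
nitrate_reduction	Resource Use	Denitrification	NO3 to NO2	resource use	binary	denitrification_step1	.
nitrite_reduction	Resource Use	Denitrification	NO2 to NO	resource use	binary	denitrification_step2	.
nitric_oxide_reduction	Resource Use	Denitrification	NO to N2O	resource use	binary	denitrification_step3	.
nitrous_oxide_reduction	Resource Use	Denitrification	N2O to N2	resource use	binary	denitrification_step4	.
monosaccharide_uptake	Resource Acquisition	Substrate uptake	Monosaccharides	resource acquisition	count	xylFGH_transporter;ptsG	monosaccharides
disaccharide_uptake	Resource Acquisition	Substrate uptake	Disaccharides	resource acquisition	count	malEFGK_transporter	disaccharides
ammonium_uptake	Resource Acquisition	Substrate uptake	Nitrogen compounds	resource acquisition	count	amtB	nitrogen_compounds
chaperone_system	Stress Tolerance	General stress	Chaperones	stress tolerance	binary	chaperone_general	.
ros_scavenging	Stress Tolerance	Oxidative stress	ROS scavenging	stress tolerance	binary	oxidative_stress_defense	.
trehalose_osmolyte	Stress Tolerance	Osmotic stress	Trehalose synthesis	stress tolerance	binary	trehalose_synthesis	.
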