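#traitguilds-manifest v1
hmm_name	trusted_cutoff	cross_refs	substrates
narG	500	K00370;EC:1.7.5.1	.
narH	300	K00371;EC:1.7.5.1	.
narI	100	K00374;EC:1.7.5.1	.
napA	400	K02567;EC:1.9.6.1	.
napB	80	K02568;EC:1.9.6.1	.
nirS	250	K15864;EC:1.7.2.1	.
nirK	150	K00368;EC:1.7.2.1	.
norB	200	K04561;EC:1.7.2.5	.
norC	90	K02305;EC:1.7.2.5	.
norV	220	K12264	.
norW	120	K12265	.
nosZ	300	K00376;EC:1.7.2.4	.
ptsG	180	K02779;TC:4.A.1.1.1	glucose:monosaccharides
xylF	160	K10543;TC:3.A.1.2.4	xylose:monosaccharides
xylG	170	K10544;TC:3.A.1.2.4	xylose:monosaccharides
xylH	140	K10545;TC:3.A.1.2.4	xylose:monosaccharides
malE	150	K10108;TC:3.A.1.1.1	maltose:disaccharides
malF	140	K10109;TC:3.A.1.1.1	maltose:disaccharides
malG	130	K10110;TC:3.A.1.1.1	maltose:disaccharides
malK	160	K10111;TC:3.A.1.1.1	maltose:disaccharides
amtB	170	K03320;TC:1.A.11.2.1	ammonium:nitrogen_compounds
dnaK	350	K04043	.
groEL	400	K04077	.
katE	300	K03781;EC:1.11.1.6	.
sodA	120	K04564;EC:1.15.1.1	.
otsA	250	K00697;EC:2.4.1.15	.
otsB	150	K01087;EC:3.1.3.12	.
rplA	120	K02863	.
rplB	140	K02886	.
rplC	110	K02906	.
rplD	100	K02926	.
rplE	95	K02931	.
rplF	90	K02933	.
rpsB	130	K02967	.
rpsC	120	K02982	.
rpsD	110	K02986	.
rpsE	90	K02988	.
rpsG	85	K02992	.
rpsK	70	K02948	.
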