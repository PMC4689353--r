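# Stem/sub-stem lexicon: WHO-style stem taxonomy fragments for name auditing.
# Spellings are stored without hyphens; affix_class is per spelling row.
# requires_parent=TRUE gates a sub-stem to names where its hyperonym matches
# directly (used for the single-letter monoclonal-antibody infixes).
stem_id	spelling	affix_class	parent	definition	requires_parent	position_sense_key	position_sense_text
ast	ast	suffix		antiasthmatics or antiallergics, not acting primarily as antihistaminics	FALSE		
lukast	lukast	suffix	ast	leukotriene receptor antagonists	FALSE		
milast	milast	suffix	ast	phosphodiesterase type IV (PDE IV) inhibitors	FALSE		
trodast	trodast	suffix	ast	thromboxane A-2 receptor antagonists, antiasthmatics	FALSE		
zolast	zolast	suffix	ast	leukotriene biosynthesis inhibitors	FALSE		
vir	vir	freefix		antivirals	FALSE		
amivir	amivir	suffix	vir	neuraminidase inhibitors	FALSE		
asvir	asvir	suffix	vir	hepatitis C virus NS5A inhibitors	FALSE		
buvir	buvir	suffix	vir	RNA polymerase (NS5B) inhibitors	FALSE		
cavir	cavir	suffix	vir	carbocyclic nucleosides	FALSE		
ciclovir	ciclovir	suffix	vir	bicyclic heterocycle compounds	FALSE		
fovir	fovir	suffix	vir	phosphonic acid derivatives	FALSE		
gosivir	gosivir	suffix	vir	glucoside inhibitors	FALSE		
navir	navir	suffix	vir	HIV protease inhibitors	FALSE		
previr	previr	suffix	vir	hepatitis C virus protease inhibitors	FALSE		
virine	virine	suffix	vir	non-nucleoside reverse transcriptase inhibitors	FALSE		
viroc	viroc	suffix	vir	CCR5 receptor antagonists	FALSE		
mab	mab	suffix		monoclonal antibodies	FALSE		
mab_src_rat	a	infix	mab	source class: rat	TRUE		
mab_src_rat_mouse	axo	infix	mab	source class: rat/mouse	TRUE		
mab_src_hamster	e	infix	mab	source class: hamster	TRUE		
mab_src_primate	i	infix	mab	source class: primate	TRUE		
mab_src_mouse	o	infix	mab	source class: mouse	TRUE		
mab_src_human	u	infix	mab	source class: human	TRUE		
mab_src_chimeric	xi	infix	mab	source class: chimeric	TRUE		
mab_src_chimeric_humanized	xizu	infix	mab	source class: chimeric/humanized	TRUE		
mab_src_humanized	zu	infix	mab	source class: humanised	TRUE		
mab_tgt_bacterial	ba	infix	mab	target class: bacterial	TRUE		
mab_tgt_bacterial	b	infix	mab	target class: bacterial	TRUE		
mab_tgt_cardiovascular	ci	infix	mab	target class: cardiovascular	TRUE		
mab_tgt_cardiovascular	c	infix	mab	target class: cardiovascular	TRUE		
mab_tgt_fungal	fu	infix	mab	target class: fungal	TRUE		
mab_tgt_fungal	f	infix	mab	target class: fungal	TRUE		
mab_tgt_interleukin	ki	infix	mab	target class: interleukin	TRUE		
mab_tgt_interleukin	k	infix	mab	target class: interleukin	TRUE		
mab_tgt_immune	li	infix	mab	target class: immunomodulating	TRUE		
mab_tgt_immune	l	infix	mab	target class: immunomodulating	TRUE		
mab_tgt_neural	ne	infix	mab	target class: neural	TRUE		
mab_tgt_neural	n	infix	mab	target class: neural	TRUE		
mab_tgt_bone	so	infix	mab	target class: bone	TRUE		
mab_tgt_bone	s	infix	mab	target class: bone	TRUE		
mab_tgt_toxin	toxa	infix	mab	target class: toxin	TRUE		
mab_tgt_toxin	tox	infix	mab	target class: toxin	TRUE		
mab_tgt_tumour	tu	infix	mab	target class: tumour	TRUE		
astine	astine	suffix		antihistaminics, histamine-H1 receptor antagonists	FALSE		
azepide	azepide	suffix		cholecystokinin receptor antagonists	FALSE		
cromil	cromil	suffix		antiallergics, cromoglicic acid derivatives	FALSE		
fenin	fenin	suffix		diagnostic aids; (phenylcarbamoyl)methyl iminodiacetic acid derivatives	FALSE		
fenine	fenine	suffix		analgesics, glafenine derivatives	FALSE		
profen	profen	suffix		anti-inflammatory agents, ibuprofen derivatives	FALSE		
profen	profene	suffix		anti-inflammatory agents, ibuprofen derivatives	FALSE		
tiptiline	tiptiline	suffix		tricyclic antidepressants	FALSE		
tiptiline	iptiline	suffix		tricyclic antidepressants	FALSE		
dipine	dipine	suffix		calcium channel blockers, 1,4-dihydropyridine derivatives	FALSE		
pine	pine	suffix		tricyclic compounds	FALSE		
micin	micin	suffix		antibacterials derived from Micromonospora strains	FALSE		
mycin	mycin	suffix		antibacterials derived from Streptomyces strains	FALSE		
nico	nico	infix		nicotinic acid or nicotinoyl alcohol derivatives	FALSE		
nico	nic	infix		nicotinic acid or nicotinoyl alcohol derivatives	FALSE		
gli	gli	freefix		antihyperglycaemics	FALSE		
grel	grel	freefix		platelet aggregation inhibitors	FALSE		
fos	fos	freefix		insecticides, anthelminthics, pesticides etc., phosphorus derivatives	FALSE	suffix	insecticides, anthelminthics, pesticides etc., phosphorus derivatives
fos	fos	freefix		insecticides, anthelminthics, pesticides etc., phosphorus derivatives	FALSE	infix	various pharmacological categories belonging to fos, other than insecticides, anthelminthics, pesticides
fos	fos	freefix		insecticides, anthelminthics, pesticides etc., phosphorus derivatives	FALSE	prefix	various pharmacological categories belonging to fos, other than insecticides, anthelminthics, pesticides
tide	tide	suffix		peptides and glycopeptides	FALSE		
actide	actide	suffix		synthetic polypeptides with a corticotrophin-like action	FALSE		
orex	orex	suffix		anorexics	FALSE		
arte	arte	prefix		antimalarial agents, artemisinin related compounds	FALSE		
sal	sal	prefix		analgesic anti-inflammatories, salicylic acid derivatives	FALSE		
salazo	salazo	prefix	sal	phenylazosalicylic acid derivatives, antibacterial	FALSE		
sulfa	sulfa	freefix		anti-infectives, sulfonamides	FALSE		
kacin	kacin	suffix		antibiotics obtained from Streptomyces kanamyceticus	FALSE		
metasone	metasone	suffix		corticosteroids, betamethasone derivatives	FALSE		
metasone	methasone	suffix		corticosteroids, betamethasone derivatives	FALSE		
setron	setron	suffix		serotonin 5-HT3 receptor antagonists	FALSE		
prist	prist	infix		steroids, progesterone receptor modulators	FALSE		
nab	nab	freefix		cannabinoid receptor agonists	FALSE		
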