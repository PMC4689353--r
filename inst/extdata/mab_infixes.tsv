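# Monoclonal-antibody name infixes: role is "target" (disease/target class)
# or "source" (species/engineering origin of the immunoglobulin sequence).
# Target infixes have an optional vowel that is kept before consonant-initial
# sources and dropped before vowel-initial ones; `spelling` is the
# vowel-bearing form, `bare` the vowel-less form (empty for sources).
# Provenance note: the tumour target infix "tu" is included although some
# printed infix lists omit it; canonical decompositions such as
# tras|tu|zu|mab require it.
role	spelling	bare	meaning	example
source	a		rat	
source	axo		rat/mouse	catumaxomab
source	e		hamster	
source	i		primate	
source	o		mouse	solitomab
source	u		human	namilumab
source	xi		chimeric	pagibaximab
source	xizu		chimeric/humanized	otelixizumab
source	zu		humanised	natalizumab
target	ba	b	bacterial	tefibazumab
target	ci	c	cardiovascular	volociximab
target	fu	f	fungal	
target	ki	k	interleukin	lebrikizumab
target	li	l	immunomodulating	infliximab
target	ne	n	neural	atinumab
target	so	s	bone	romosozumab
target	toxa	tox	toxin	urtoxazumab
target	tu	tu	tumour	trastuzumab
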