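# sent_id = sciatica_example
1	sciatica	sciatica	NOUN	_	_	8	nsubjpass	_	_
2	in	in	ADP	_	_	5	case	_	_
3	low	low	ADJ	_	_	5	amod	_	_
4	back	back	NOUN	_	_	5	compound	_	_
5	pain	pain	NOUN	_	_	1	nmod	_	_
6	is	be	AUX	_	_	8	auxpass	_	_
7	usually	usually	ADV	_	_	8	advmod	_	_
8	caused	cause	VERB	_	_	0	root	_	_
9	by	by	ADP	_	_	11	case	_	_
10	disc	disc	NOUN	_	_	11	compound	_	_
11	herniation	herniation	NOUN	_	_	8	nmod	_	_
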