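# Published per-word predictability values for two example sentences from each
# of the Schilling sentence corpus (SRC, English) and the Potsdam sentence
# corpus (PSC, German): empirical cloze completion probability (ccp) and the
# n-gram, topic and RNN model probabilities, printed at one significant figure.
dataset	sentence	word	ccp	ngram	topic	rnn
SRC	1	Bill	6e-3	1e-4	1e-3	2e-5
SRC	1	complained	6e-3	3e-6	1e-4	1e-6
SRC	1	that	3e-1	1e-1	2e-3	6e-2
SRC	1	the	2e-1	1e-1	2e-3	1e-2
SRC	1	magazine	6e-3	1e-4	3e-4	3e-5
SRC	1	included	6e-3	3e-7	2e-4	1e-5
SRC	1	more	6e-3	4e-4	2e-3	6e-4
SRC	1	adds	4e-1	6e-7	2e-5	1e-8
SRC	1	than	9e-1	2e-4	2e-3	1e-3
SRC	1	articles	8e-1	4e-6	5e-5	4e-6
SRC	2	The	6e-3	6e-4	3e-3	2e-2
SRC	2	drunk	6e-3	6e-5	9e-4	2e-5
SRC	2	driver	6e-3	2e-2	2e-4	2e-3
SRC	2	lost	6e-3	6e-6	2e-3	1e-5
SRC	2	control	4e-1	4e-1	3e-3	6e-3
SRC	2	crashed	5e-2	9e-8	1e-4	4e-7
SRC	2	into	4e-1	9e-2	2e-3	1e-1
SRC	2	a	6e-1	2e-1	2e-3	1e-1
SRC	2	street	6e-3	9e-4	2e-3	4e-3
SRC	2	sign	6e-1	2e-2	3e-3	6e-4
SRC	2	and	8e-1	1e-3	2e-3	3e-3
SRC	2	died	7e-1	3e-5	2e-3	4e-4
PSC	1	In	1e-2	2e-3	3e-2	4e-3
PSC	1	der	7e-1	1e-1	1e-2	1e-1
PSC	1	Klosterschule	6e-3	2e-6	4e-5	4e-5
PSC	1	herrschen	2e-2	1e-6	8e-4	3e-4
PSC	1	Schwester	6e-3	5e-5	4e-2	1e-9
PSC	1	Agathe	1e-2	7e-7	1e-4	1e-8
PSC	1	und	9e-1	5e-3	4e-3	4e-2
PSC	1	Schwester	5e-1	1e-4	2e-2	8e-5
PSC	1	Maria	1e-1	5e-4	2e-3	2e-3
PSC	2	Er	6e-3	1e-2	2e-2	2e-2
PSC	2	hätte	6e-3	5e-3	2e-3	2e-3
PSC	2	nicht	2e-2	4e-2	2e-2	3e-2
PSC	2	auch	6e-3	3e-4	9e-4	4e-3
PSC	2	noch	7e-1	1e-1	1e-3	3e-2
PSC	2	am	1e-2	3e-3	3e-3	5e-3
PSC	2	Telefon	6e-3	4e-3	4e-3	4e-2
PSC	2	nörgeln	6e-3	8e-8	5e-5	6e-8
PSC	2	sollen	7e-1	2e-4	2e-3	6e-4
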