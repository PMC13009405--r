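surface	lemma
children	child
child's	child
men	man
women	woman
feet	foot
teeth	tooth
mice	mouse
people	person
dishes	dish
cookies	cookie
cookie's	cookie
movies	movie
pies	pie
ties	tie
knives	knife
leaves	leaf
shelves	shelf
loaves	loaf
stole	steal
stolen	steal
took	take
taken	take
fell	fall
fallen	fall
ran	run
running	run
gave	give
given	give
got	get
gotten	get
stood	stand
standing	stand
sat	sit
sitting	sit
broke	break
broken	break
went	go
gone	go
goes	go
did	do
done	do
does	do
said	say
saw	see
seen	see
made	make
began	begin
begun	begin
spilt	spill
overflowed	overflow
overflowing	overflow
dried	dry
drying	dry
drops	drop
dropped	drop
dropping	drop
slipped	slip
slipping	slip
grabbed	grab
grabbing	grab
tipped	tip
tipping	tip
wobbled	wobble
wobbling	wobble
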