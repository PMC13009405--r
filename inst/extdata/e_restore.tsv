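stem	lemma
tak	take
mak	make
giv	give
stor	store
wash	wash
reach	reach
wip	wipe
bak	bake
ris	rise
us	use
overflow	overflow
dri	dry
wav	wave
shak	shake
serv	serve
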