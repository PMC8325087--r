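# Demonstration word-polarity lexicon: high-frequency emotion words of
# depression-forum language with hand-assigned signed scores in [-1, 1].
good	0.7
great	0.8
happy	0.8
happiness	0.8
love	0.9
loved	0.8
hope	0.7
fun	0.7
nice	0.6
enjoy	0.7
better	0.5
best	0.7
friend	0.5
friends	0.5
friendship	0.6
family	0.4
care	0.5
help	0.5
advice	0.3
support	0.6
calm	0.5
comfort	0.6
grateful	0.8
proud	0.7
relief	0.6
motivation	0.5
okay	0.3
fine	0.3
normal	0.2
together	0.3
believe	0.3
understand	0.3
birthday	0.4
married	0.4
baby	0.3
smile	0.7
laugh	0.7
beautiful	0.7
wonderful	0.8
amazing	0.8
excited	0.7
joy	0.9
peace	0.7
success	0.6
win	0.5
horrible	-0.8
die	-0.9
died	-0.8
dying	-0.8
dead	-0.8
death	-0.8
stupid	-0.6
sick	-0.4
fool	-0.5
hate	-0.8
shitty	-0.7
shit	-0.6
fuck	-0.6
fucking	-0.6
bad	-0.5
worse	-0.6
worst	-0.8
sad	-0.7
cry	-0.7
crying	-0.7
tired	-0.4
alone	-0.6
lonely	-0.8
depressed	-0.9
depression	-0.9
anxiety	-0.7
anxious	-0.7
suicide	-0.95
suicidal	-0.95
kill	-0.9
hurt	-0.7
pain	-0.7
painful	-0.7
afraid	-0.6
scared	-0.7
fear	-0.7
angry	-0.7
upset	-0.6
annoyed	-0.5
miserable	-0.8
hopeless	-0.9
worthless	-0.9
useless	-0.8
broken	-0.7
broke	-0.5
lost	-0.5
lose	-0.5
wrong	-0.4
problem	-0.4
problems	-0.4
issues	-0.4
fault	-0.5
guilt	-0.7
guilty	-0.7
shame	-0.7
ashamed	-0.7
hell	-0.6
toxic	-0.7
cancer	-0.7
illness	-0.5
hospital	-0.3
therapy	-0.2
dark	-0.4
empty	-0.6
numb	-0.6
struggle	-0.6
struggling	-0.6
fail	-0.6
failure	-0.7
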