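bad
worse
worst
awful
terrible
horrible
miserable
scared
angry
unhappy
useless
dreadful
failed
nasty
frustrating
disappointing
fear
hate
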