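good
great
better
best
improved
improving
relief
helpful
happy
grateful
thankful
amazing
wonderful
love
fantastic
encouraging
hopeful
success
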