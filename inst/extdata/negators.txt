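# polarity-flipping tokens (window: 3 preceding tokens)
not
no
never
neither
nor
cannot
can't
don't
doesn't
didn't
won't
wouldn't
couldn't
shouldn't
isn't
wasn't
aren't
weren't
ain't
without
rarely
seldom
hardly
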