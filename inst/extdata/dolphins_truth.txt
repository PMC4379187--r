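Beak Bumper CCL Cross Double Fish Five Fork Grin Haecksel Hook Jonah Kringel MN105 MN23 MN60 MN83 Oscar Patchback PL Scabs Shmuddel SMN5 SN100 SN4 SN63 SN9 SN96 Stripes Thumper Topless TR120 TR77 TR82 TR88 TR99 Trigger TSN103 TSN83 Vau Whitetip Zap Zipfel
Beescratch DN16 DN21 DN63 Feather Gallatin Jet Knit Mus Notch Number1 Quasi Ripplefluke SN89 SN90 Upbang Wave Web Zig
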