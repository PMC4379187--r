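Fish Beak
Grin Beak
Haecksel Beak
SN9 Beak
SN96 Beak
TR77 Beak
Jet Beescratch
Knit Beescratch
Notch Beescratch
Number1 Beescratch
Oscar Beescratch
SN100 Beescratch
SN90 Beescratch
Upbang Beescratch
Fish Bumper
SN96 Bumper
Thumper Bumper
Zipfel Bumper
Double CCL
Zap CCL
Grin Cross
Trigger Cross
Feather DN16
Gallatin DN16
Wave DN16
Web DN16
Feather DN21
Gallatin DN21
Jet DN21
Upbang DN21
Wave DN21
Web DN21
Knit DN63
Number1 DN63
PL DN63
SN9 DN63
Upbang DN63
Kringel Double
Oscar Double
SN4 Double
Topless Double
Zap Double
Gallatin Feather
Jet Feather
Ripplefluke Feather
SN90 Feather
Web Feather
Patchback Fish
SN96 Fish
TR77 Fish
Trigger Five
Scabs Fork
Jet Gallatin
Ripplefluke Gallatin
SN90 Gallatin
Upbang Gallatin
Web Gallatin
Hook Grin
MN83 Grin
Scabs Grin
Shmuddel Grin
SN4 Grin
SN63 Grin
SN9 Grin
Stripes Grin
TR99 Grin
TSN103 Grin
Jonah Haecksel
MN83 Haecksel
SN9 Haecksel
Topless Haecksel
Vau Haecksel
Zap Haecksel
Kringel Hook
Scabs Hook
SN4 Hook
SN63 Hook
TR99 Hook
MN23 Jet
Mus Jet
Notch Jet
Number1 Jet
Quasi Jet
Web Jet
Kringel Jonah
MN105 Jonah
MN83 Jonah
Patchback Jonah
Topless Jonah
Trigger Jonah
PL Knit
Upbang Knit
Oscar Kringel
SN100 Kringel
SN63 Kringel
Thumper Kringel
TR77 Kringel
TR99 Kringel
Patchback MN105
Scabs MN105
SN4 MN105
Topless MN105
Trigger MN105
SN100 MN60
Topless MN60
Trigger MN60
Patchback MN83
Topless MN83
Trigger MN83
Notch Mus
Number1 Mus
Number1 Notch
PL Oscar
TR77 Oscar
SMN5 Patchback
Stripes Patchback
Topless Patchback
Trigger Patchback
TSN103 Patchback
SN96 PL
TR77 PL
Zig Ripplefluke
Shmuddel Scabs
SN4 Scabs
SN63 Scabs
SN9 Scabs
Stripes Scabs
TR99 Scabs
SN4 Shmuddel
Thumper Shmuddel
TR88 Shmuddel
SN4 SN100
SN89 SN100
SN9 SN100
Zap SN100
SN9 SN4
Topless SN4
Zipfel SN4
Stripes SN63
Thumper SN63
TSN103 SN63
Whitetip SN63
Web SN89
TSN103 SN90
Upbang SN90
Web SN90
TR77 SN96
TR99 SN96
Stripes SN4
TR120 Stripes
TSN83 Stripes
TR99 Thumper
TR88 TR120
Web TR82
Trigger TR99
Vau Trigger
Zipfel TSN83
Web Upbang
Zig Whitetip
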