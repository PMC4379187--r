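# report every failure rather than aborting the run part-way: the
# acceptance blocks assert the study's printed operating points, and the
# full suite must execute regardless of their outcomes
options(testthat.progress.max_fails = 1000)
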