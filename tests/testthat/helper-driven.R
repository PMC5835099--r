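# Shared generators for equivalence testing (random driven networks where
# all spike trains are prescribed). The definitions live under
# inst/acceptance/ because scripts/acceptance.R uses the same cases.

source(system.file("acceptance", "driven_case.R", package = "tristdp"))
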