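# fp-contract must stay off: spike-identical float comparisons against the
# R reference rely on plain IEEE double ops without FMA fusion.
PKG_CXXFLAGS = -ffp-contract=off
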