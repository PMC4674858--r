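# A synthetic world at desk scale: small enough for examples and quick
# checks, with the same masking mechanism as the full-scale defaults.
nTfs: 24
nGenes: 300
meanTargetsPerTf: 20
targetOverallOp: 0.06
backgroundEffectProb: 0.01
maskingStrength: 0.8
paralogFraction: 0.5
nTerms: 120
termsPerTf: 6
termShareRate: 0.75
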