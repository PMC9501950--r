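# Example pipeline configuration (key = value). Paths are resolved
# relative to the working directory of the run.
hartree_to_ev = 27.211386
donor_symbol = Na
donor_I_eV = 5.139
donor_A_eV = 0.548
acceptor_symbol = F
acceptor_I_eV = 17.423
acceptor_A_eV = 3.401
rd_boundary = 1.0
ra_boundary = 1.0
assay_model = loglinear_interpolation
correlation_descriptor = I_eV
convention = replication
seed = 1
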