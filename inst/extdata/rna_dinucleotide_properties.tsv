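# RNA dinucleotide physicochemical properties used by the pseudo dinucleotide
# composition (PseDNC) encoder. schema_version: 1
# free_energy: Turner nearest-neighbor Gibbs free energy increments
#   (kcal/mol, 37 C) for 5'->3' dinucleotide stacks.
# stacking_energy: base-stacking energy compilation (kcal/mol) as circulated
#   in the RNA pseudo-composition literature.
# hydrophilicity: dinucleotide hydrophilicity compilation as circulated in the
#   RNA pseudo-composition literature.
# Values are standardized to zero mean / unit variance over the 16
# dinucleotides before use; any user-supplied table with these columns can be
# substituted via psednc_config(properties = ...).
dinucleotide	free_energy	stacking_energy	hydrophilicity
AA	-0.93	-13.7	0.023
AU	-1.10	-15.4	0.090
AC	-2.24	-13.8	0.083
AG	-2.08	-14.0	0.035
UA	-1.33	-16.0	0.112
UU	-0.93	-13.7	0.389
UC	-2.35	-14.2	0.359
UG	-2.11	-14.4	0.224
CA	-2.11	-14.4	0.118
CU	-2.08	-14.0	0.378
CC	-3.26	-11.1	0.349
CG	-2.36	-15.6	0.193
GA	-2.35	-14.2	0.048
GU	-2.24	-13.8	0.160
GC	-3.42	-16.9	0.146
GG	-3.26	-11.1	0.065
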