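# Curated KO identifiers of auxiliary metabolic enzymes commonly carried
# by human-gut bacteriophages (one KO per line).
K00558  # DNA-cytosine methyltransferase
K00986  # RNA-directed DNA polymerase
K01520  # dUTP pyrophosphatase
K01185  # lysozyme
K00390  # phosphoadenosine phosphosulfate reductase
K00957  # sulfate adenylyltransferase
K21471  # peptidoglycan DL-endopeptidase
K00789  # S-adenosylmethionine synthetase
K22409  # N-acetylmuramoyl-L-alanine amidase
K01447  # N-acetylmuramoyl-L-alanine amidase (autolysin)
K01449  # endolysin
K17733  # cell wall hydrolase
K01916  # NAD+ synthase
K00969  # nicotinate-nucleotide adenylyltransferase
K08281  # nicotinamidase (pncA)
K00763  # nicotinate phosphoribosyltransferase (pncB)
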