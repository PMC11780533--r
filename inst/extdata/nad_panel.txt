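# Enzymes of NAD+ de novo biosynthesis and salvage pathways carried by
# gut phages (one KO per line).
K01916  # NAD+ synthase (de novo biosynthesis)
K00969  # nicotinate-nucleotide adenylyltransferase (salvage I/II)
K08281  # nicotinamidase pncA (salvage I/V)
K00763  # nicotinate phosphoribosyltransferase pncB (salvage I/V)
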