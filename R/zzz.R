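.datatable.aware <- TRUE

utils::globalVariables(c("chrom", "start", "end", "barcode", "count",
                         "n_cell_types", "n_cells_per_type", "n_peaks",
                         "n_specific_peaks_per_type", "p0", "p1", "n_genes",
                         "n_marker_genes_per_type", "rna_nb_mean",
                         "rna_nb_dispersion", "activity_mean", "mito_fraction",
                         "promoter_fragment_fraction", "contaminant_fraction",
                         "snp_in_peak_fraction", "cells_per_stage",
                         "n_transition_peaks_per_edge", "n_snps",
                         "n_blacklist", "genome", "stage_graph", "seed"))
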