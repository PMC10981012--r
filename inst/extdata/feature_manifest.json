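[
  {
    "name": "seed_canonical_2_7",
    "type": "boolean",
    "description": "canonical seed pairing in the window"
  },
  {
    "name": "seed_canonical_3_8",
    "type": "boolean",
    "description": "canonical seed pairing in the window"
  },
  {
    "name": "seed_noncanonical_2_7",
    "type": "boolean",
    "description": "non-canonical seed pairing in the window"
  },
  {
    "name": "seed_noncanonical_3_8",
    "type": "boolean",
    "description": "non-canonical seed pairing in the window"
  },
  {
    "name": "seed_type_canonical",
    "type": "boolean",
    "description": "overall seed class is canonical"
  },
  {
    "name": "seed_type_noncanonical",
    "type": "boolean",
    "description": "overall seed class is non-canonical"
  },
  {
    "name": "wc_pairs_seed",
    "type": "numeric",
    "description": "Watson-Crick pairs in the miRNA region"
  },
  {
    "name": "gu_pairs_seed",
    "type": "numeric",
    "description": "GU wobble pairs in the miRNA region"
  },
  {
    "name": "unpaired_seed",
    "type": "numeric",
    "description": "unpaired miRNA positions in the region"
  },
  {
    "name": "wc_pairs_central",
    "type": "numeric",
    "description": "Watson-Crick pairs in the miRNA region"
  },
  {
    "name": "gu_pairs_central",
    "type": "numeric",
    "description": "GU wobble pairs in the miRNA region"
  },
  {
    "name": "unpaired_central",
    "type": "numeric",
    "description": "unpaired miRNA positions in the region"
  },
  {
    "name": "wc_pairs_comp",
    "type": "numeric",
    "description": "Watson-Crick pairs in the miRNA region"
  },
  {
    "name": "gu_pairs_comp",
    "type": "numeric",
    "description": "GU wobble pairs in the miRNA region"
  },
  {
    "name": "unpaired_comp",
    "type": "numeric",
    "description": "unpaired miRNA positions in the region"
  },
  {
    "name": "duplex_score",
    "type": "numeric",
    "description": "total duplex score (arbitrary units)"
  },
  {
    "name": "n_paired",
    "type": "numeric",
    "description": "number of paired bases in the duplex"
  },
  {
    "name": "frac_mirna_paired",
    "type": "numeric",
    "description": "fraction of miRNA positions paired"
  },
  {
    "name": "longest_wc_run",
    "type": "numeric",
    "description": "longest run of consecutive WC pairs"
  },
  {
    "name": "site_freq_A",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_C",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_G",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_U",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_AA",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_CA",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_GA",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_UA",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_AC",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_CC",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_GC",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_UC",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_AG",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_CG",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_GG",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_UG",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_AU",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_CU",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_GU",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_freq_UU",
    "type": "numeric",
    "description": "site mono-/di-nucleotide frequency"
  },
  {
    "name": "site_au_content",
    "type": "numeric",
    "description": "A+U fraction of the site"
  },
  {
    "name": "site_gc_content",
    "type": "numeric",
    "description": "G+C fraction of the site"
  },
  {
    "name": "site_length",
    "type": "numeric",
    "description": "site length in nt"
  },
  {
    "name": "site_rel_position",
    "type": "numeric",
    "description": "site start / UTR length (0 without context)"
  },
  {
    "name": "mirna_length",
    "type": "numeric",
    "description": "miRNA length in nt"
  },
  {
    "name": "mirna_gc_content",
    "type": "numeric",
    "description": "G+C fraction of the miRNA"
  },
  {
    "name": "mirna_freq_A",
    "type": "numeric",
    "description": "miRNA mononucleotide frequency"
  },
  {
    "name": "mirna_freq_C",
    "type": "numeric",
    "description": "miRNA mononucleotide frequency"
  },
  {
    "name": "mirna_freq_G",
    "type": "numeric",
    "description": "miRNA mononucleotide frequency"
  },
  {
    "name": "mirna_freq_U",
    "type": "numeric",
    "description": "miRNA mononucleotide frequency"
  }
]
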