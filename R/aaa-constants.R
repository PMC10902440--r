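# package-wide constants

SUMSTATS_COLS <- c("snp", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# non-palindromic allele pairs: generated variants are strand-unambiguous
# by construction so harmonization retains them all
NONPAL_PAIRS <- do.call(rbind, Filter(
  function(p) p[1] != p[2] && BASE_COMPLEMENT[p[1]] != p[2],
  apply(expand.grid(BASES, BASES, stringsAsFactors = FALSE), 1, as.character,
        simplify = FALSE)))
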