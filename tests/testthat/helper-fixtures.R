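# Shared in-code fixtures: tiny deterministic objects used across test files.

make_groups <- function(n_lines = 3L) {
  g <- expand.grid(line = seq_len(n_lines), state = c("iPSC", "CM"),
                   genotype = c("WT", "TS"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_L%02d", g$genotype, g$state, g$line),
             genotype = g$genotype, state = g$state,
             line_id = sprintf("%s_L%02d", g$genotype, g$line),
             stringsAsFactors = FALSE)
}

# small random linear-scale matrix over the standard 12-sample design
make_em <- function(n_features = 20L, n_lines = 3L, seed = 1L,
                    scale = "linear") {
  set.seed(seed)
  groups <- make_groups(n_lines)
  v <- matrix(2^rnorm(n_features * nrow(groups), 8, 1),
              nrow = n_features,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              groups$sample_id))
  if (scale == "log2") v <- log2(v)
  expression_matrix(v, groups, scale)
}

# matrix with arbitrary sample metadata for plain numeric tests
make_simple_em <- function(values, scale = "log2") {
  stopifnot(is.matrix(values))
  n <- ncol(values)
  groups <- data.frame(sample_id = colnames(values),
                       genotype = rep("WT", n),
                       state = rep("iPSC", n),
                       line_id = paste0("L", seq_len(n)),
                       stringsAsFactors = FALSE)
  expression_matrix(values, groups, scale)
}

named_matrix <- function(data, nrow, features = NULL, samples = NULL) {
  m <- matrix(data, nrow = nrow)
  rownames(m) <- features %||% paste0("f", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force hypergeometric upper tail by exhaustive enumeration of draws;
# usable for universes up to ~12
enum_hypergeom_upper <- function(overlap, k_annot, k_query, universe) {
  if (overlap == 0L) return(1)
  universe_ids <- seq_len(universe)
  annot <- seq_len(k_annot)
  draws <- utils::combn(universe_ids, k_query)
  hits <- apply(draws, 2L, function(d) sum(d %in% annot) >= overlap)
  mean(hits)
}
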