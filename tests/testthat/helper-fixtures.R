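# Shared fixtures. Expensive objects are built once per test run and
# memoized; everything is a pure function of the seeds fixed here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-condition simulation shared across tests
default_sim <- function() memo("default_sim", function() {
  simulate_sc_counts(sim_config(seed = 101L))
})

# QC-filtered normalized view of the default simulation
default_norm <- function() memo("default_norm", function() {
  sim <- default_sim()
  sets <- sim$truth$program_gene_sets
  keep <- filter_cells(sim$counts, qc_params(mito_genes = sets$mito,
                                             dissoc_genes = sets$dissoc))
  counts <- sim$counts[, keep, drop = FALSE]
  list(counts = counts, norm = lognormalize(counts),
       cell_types = sim$truth$cell_type_labels[colnames(counts)],
       sim = sim)
})

# a full default pipeline run shared by the end-to-end tests
default_run <- function() memo("default_run", function() {
  suppressMessages(run_all(pipeline_config(
    file.path(tempdir(), "default_run"), seed = 5L)))
})

# small random normalized matrix for oracle tests
random_norm <- function(ng, nc, seed) {
  set.seed(seed)
  m <- matrix(stats::rpois(ng * nc, 3), ng, nc,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("c%03d", seq_len(nc))))
  lognormalize(m)
}

# a hand-buildable probe table: one pool, explicit counts
toy_probe_table <- function(counts, targets, n_neg = 2, neg_value = 10,
                            total_reads = NULL) {
  probe_ids <- paste0("p", seq_len(ncol(counts)))
  colnames(counts) <- probe_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("A%02d", seq_len(nrow(counts)))
  neg <- matrix(neg_value, nrow(counts), n_neg,
                dimnames = list(rownames(counts), paste0("n", seq_len(n_neg))))
  all_counts <- cbind(counts, neg)
  map <- data.frame(probe_id = colnames(all_counts),
                    target = c(targets, rep("NEGATIVE", n_neg)),
                    pool = "P1", stringsAsFactors = FALSE)
  if (is.null(total_reads)) total_reads <- rowSums(all_counts)
  meta <- data.frame(aoi_id = rownames(all_counts), sample = "S",
                     compartment = "tumor", morphology = "nodular",
                     total_reads = total_reads, stringsAsFactors = FALSE)
  probe_count_table(all_counts, map, meta)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# independent brute-force Moran's I (double sum over the weight matrix)
brute_morans_i <- function(x, w) {
  w <- as.matrix(w)
  diag(w) <- 0
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}
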