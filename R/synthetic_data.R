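# Template curves on the normalized time scale u in [0, 1], values on the
# normalized CSMS scale [0, 1]. The bump shapes emulate a pollen season
# peaking in the first half of the window.
season_bump <- function(u, center = 0.38, width = 0.2) {
  exp(-((u - center) / width)^2)
}

# Template levels are set so the three canonical cluster shapes are
# mutually comparably separated in L2 over the window (the bump only spans
# part of the season, so its amplitude must exceed the flat-level gap for
# the planted clusters to be equally distinguishable).
template_fun <- function(shape) {
  switch(shape,
    "flat-low"  = function(u) 0.10 + 0.04 * sin(2 * pi * u),
    "flat-high" = function(u) 0.55 + 0.05 * sin(2 * pi * u),
    "peak-then-decline" = function(u) 0.65 - 0.45 * stats::plogis((u - 0.5) * 12),
    "pollen-tracking"   = function(u) 0.12 + 0.80 * season_bump(u),
    stop("unknown template shape: ", shape, call. = FALSE)
  )
}

#' Synthetic cohort design
#'
#' Describes a cohort with known cluster structure for end-to-end
#' evaluation: per-cluster smooth template curves on the normalized CSMS
#' scale, patient-level amplitude and time-shift jitter, additive Gaussian
#' noise, missing-completely-at-random days, and pollen-count curves of
#' which the first taxon tracks the `"pollen-tracking"` template. The
#' defaults emulate a 40-day seasonal study with three clusters of 30
#' patients (severe, mild, and pollen-tracking symptom profiles),
#' observation noise sd 0.05 on the \[0, 1\] scale and 10% missing days.
#'
#' @param shapes Character vector of per-cluster template names among
#'   `"flat-low"`, `"flat-high"`, `"peak-then-decline"`,
#'   `"pollen-tracking"`.
#' @param n_per_cluster Patients per cluster (recycled to `length(shapes)`).
#' @param v Number of observation days.
#' @param sigma Additive noise sd on the normalized \[0, 1\] scale.
#' @param rho MCAR missingness probability per day, in \[0, 1).
#' @param amp_sd Sd of the multiplicative patient amplitude jitter.
#' @param shift_sd Sd (days) of the patient time-shift jitter.
#' @param pollen_taxa Names of the pollen series to generate; the first is
#'   the season bump the `"pollen-tracking"` template follows, the rest
#'   are off-season or unrelated curves.
#' @param pollen_max Peak counts (grains/m^3) per taxon.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(shapes = c("flat-high", "flat-low", "pollen-tracking"),
                          n_per_cluster = 30L, v = 40L, sigma = 0.05,
                          rho = 0.1, amp_sd = 0.1, shift_sd = 1.5,
                          pollen_taxa = c("grass", "olive", "nettle"),
                          pollen_max = c(400, 200, 60), seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  for (sh in shapes) template_fun(sh)   # validates names
  structure(list(
    shapes = shapes, k_true = length(shapes),
    n_per_cluster = rep_len(as.integer(n_per_cluster), length(shapes)),
    v = as.integer(v), sigma = sigma, rho = rho, amp_sd = amp_sd,
    shift_sd = shift_sd, pollen_taxa = pollen_taxa,
    pollen_max = rep_len(pollen_max, length(pollen_taxa)), seed = seed
  ), class = "cohort_design")
}

# Decompose a raw CSMS target in [0, 6] into a consistent record:
# medication takes the part above the symptom scale (0 unless the target
# exceeds half scale), the remaining ARTSS target is spread over six
# integer symptom grades as evenly as possible. The recovered CSMS differs
# from the target by at most 1/12 (ARTSS granularity is 1/6).
decompose_csms <- function(raw) {
  if (raw < 0 || raw > 6) stop("CSMS target outside [0, 6]", call. = FALSE)
  rms <- if (raw > 3) min(3L, as.integer(ceiling(raw - 3))) else 0L
  target <- raw - rms
  total <- round(6 * target)
  base <- total %/% 6L
  rem <- total %% 6L
  sym <- rep(base, 6L) + c(rep(1L, rem), rep(0L, 6L - rem))
  list(symptoms = sym, medication = rms)
}

#' Generate a synthetic cohort of daily symptom records
#'
#' Draws each patient's latent curve as an amplitude- and shift-jittered
#' cluster template plus Gaussian noise, clipped to \[0, 1\]; decomposes
#' every daily value back into six integer symptom grades and a medication
#' category whose CSMS round-trips to the target (within the 1/6 ARTSS
#' granularity); masks days MCAR; and generates the pollen-count series.
#' Deterministic under the design seed.
#'
#' @param design A [cohort_design()].
#' @return List with `records` (long-format daily record data frame, as
#'   consumed by [score_records()]), `labels` (named integer vector of
#'   true clusters), `curves` (patients-by-days matrix of the latent
#'   normalized CSMS values), `pollen` (taxa-by-days count matrix) and
#'   `design`.
#' @export
generate_cohort <- function(design) {
  set.seed(design$seed)
  v <- design$v
  days <- seq_len(v)
  u_of <- function(day, shift) pmin(pmax((day - 1 - shift) / (v - 1), 0), 1)
  ids <- character(0); labels <- integer(0)
  curves <- NULL
  rows <- list()
  pat <- 0L
  for (g in seq_along(design$shapes)) {
    tf <- template_fun(design$shapes[g])
    for (j in seq_len(design$n_per_cluster[g])) {
      pat <- pat + 1L
      id <- sprintf("P%03d", pat)
      amp <- max(0.2, 1 + stats::rnorm(1L, 0, design$amp_sd))
      shift <- stats::rnorm(1L, 0, design$shift_sd)
      latent <- pmin(pmax(amp * tf(u_of(days, shift)) +
                            stats::rnorm(v, 0, design$sigma), 0), 1)
      miss <- stats::runif(v) < design$rho
      for (d in days) {
        if (miss[d]) next                       # missing day: no app entry
        dec <- decompose_csms(6 * latent[d])
        rows[[length(rows) + 1L]] <- c(pat = pat, day = d,
                                       dec$symptoms, med = dec$medication)
      }
      ids <- c(ids, id); labels <- c(labels, g)
      curves <- rbind(curves, latent)
    }
  }
  rec <- as.data.frame(do.call(rbind, rows))
  names(rec) <- c("pat", "day", symptom_columns(), "medication")
  records <- data.frame(patient_id = ids[rec$pat], day = rec$day,
                        rec[symptom_columns()], medication = rec$medication)
  rownames(curves) <- ids
  colnames(curves) <- days
  names(labels) <- ids
  # pollen series: taxon 1 is the in-season bump the tracking template
  # follows; the others are an early bump and a late ramp
  uu <- (days - 1) / (v - 1)
  shapes <- rbind(season_bump(uu),
                  season_bump(uu, center = 0.12, width = 0.10),
                  stats::plogis((uu - 0.75) * 14))
  pollen <- design$pollen_max[seq_along(design$pollen_taxa)] *
    shapes[seq_along(design$pollen_taxa), , drop = FALSE]
  rownames(pollen) <- design$pollen_taxa
  colnames(pollen) <- days
  list(records = records, labels = labels, curves = curves,
       pollen = pollen, design = design)
}

#' Gaussian blobs in coefficient space
#'
#' Direct fixtures for the clustering stage: `n_per_cluster` points per
#' cluster drawn around the given centers with isotropic Gaussian spread.
#'
#' @param n_per_cluster Points per cluster (recycled).
#' @param centers k-by-s matrix of cluster centers (pairwise distinct
#'   rows).
#' @param spread Gaussian sd around each center (default 1).
#' @param seed Optional integer seed.
#' @return List `C` (points-by-s matrix) and `labels`.
#' @export
generate_coefficient_blobs <- function(n_per_cluster, centers, spread = 1,
                                       seed = NULL) {
  centers <- as.matrix(centers)
  if (nrow(centers) > 1L && min(stats::dist(centers)) == 0)
    stop("cluster centers must be pairwise distinct", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(centers); s <- ncol(centers)
  n_per_cluster <- rep_len(as.integer(n_per_cluster), k)
  labels <- rep(seq_len(k), times = n_per_cluster)
  C <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * s, 0, spread), ncol = s)
  rownames(C) <- sprintf("U%03d", seq_along(labels))
  list(C = C, labels = labels)
}

#' Write synthetic cohort inputs as delimited text
#'
#' Emits the record table and the pollen counts in the same formats the
#' readers consume, plus the true labels for evaluation.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param sep Field separator (default tab).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, sep = "\t") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.tsv"),
             pollen = file.path(dir, "pollen.tsv"),
             labels = file.path(dir, "true_labels.tsv"))
  utils::write.table(cohort$records, paths["records"], sep = sep,
                     row.names = FALSE, quote = FALSE)
  pol <- data.frame(taxon = rownames(cohort$pollen), cohort$pollen,
                    check.names = FALSE)
  utils::write.table(pol, paths["pollen"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(
    data.frame(patient_id = names(cohort$labels), cluster = cohort$labels),
    paths["labels"], sep = sep, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a pollen-count table written by [write_cohort()]
#'
#' @param path File with a `taxon` column followed by day columns.
#' @param sep Field separator (default tab).
#' @return Taxa-by-days numeric matrix.
#' @export
read_pollen_counts <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
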