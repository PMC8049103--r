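# Negative-binomial bulk-count generator with exhaustion-signature
# dynamics: mu_g(arm, day) = baseline_g * 2^(beta_g * p(arm, day)) with p
# the arm's exhaustion-program level, beta > 0 for up-signature genes,
# beta < 0 for down-signature genes and 0 for background genes.

#' Default bulk RNA design: three arms, three timepoints, three donors
#'
#' Arms ALWAYS_ON, ALWAYS_OFF and RESTED_D11_15 at days 7, 11 and 15. The
#' `program` column is the exhaustion-program level p(arm, day): ALWAYS_ON
#' rises to 1 by day 15, ALWAYS_OFF stays at 0, and the rested arm tracks
#' ALWAYS_ON until day 11 and then reverses completely to baseline by day
#' 15 (transcripts of rested cells return to always-off levels).
#'
#' @param n_donors Replicate donors per arm/day.
#' @return Data frame `sample_id`, `arm`, `day`, `donor`, `program`.
#' @export
default_bulk_design <- function(n_donors = 3) {
  prog <- list(ALWAYS_ON = c(`7` = 0.33, `11` = 0.66, `15` = 1.00),
               ALWAYS_OFF = c(`7` = 0, `11` = 0, `15` = 0),
               RESTED_D11_15 = c(`7` = 0.33, `11` = 0.66, `15` = 0))
  rows <- list()
  for (arm in names(prog)) for (day in c(7, 11, 15))
    for (don in seq_len(n_donors))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("%s_D%02d_don%d", arm, day, don),
                   arm = arm, day = day, donor = don,
                   program = prog[[arm]][[as.character(day)]],
                   stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulate bulk negative-binomial counts with signature dynamics
#'
#' Gene baselines are lognormal around a median of ~100 counts; signature
#' genes respond to the arm's program level with log2 effect `beta_g`
#' (`+effect_size` for up genes, `-effect_size` for down genes, 0 for
#' background). Library sizes are uniform on `lib_range` times the nominal
#' depth implied by the baselines. Counts are `NB(mu, size = nb_dispersion)`
#' with dispersion shared across genes.
#'
#' @param design Sample sheet with `sample_id`, `arm`, `day`, `program`
#'   columns (see [default_bulk_design()]).
#' @param signatures A [signature_set()] naming the responsive genes.
#' @param n_genes Total gene count (signature + background).
#' @param effect_size Per-unit-program log2 fold change magnitude.
#' @param nb_dispersion NB size parameter (`> 0`); large values approach
#'   Poisson. The default (size 40, ~16% biological CV) reflects tight
#'   in vitro culture replicates.
#' @param lib_range Library-size factor range.
#' @param seed Integer seed; fixed seed gives identical matrices.
#' @return List with `es` (an [expr_set()]) and `truth` (data frame `gene`,
#'   `class`, `beta`, `baseline`).
#' @export
simulate_bulk_counts <- function(design = default_bulk_design(),
                                 signatures = default_signatures(),
                                 n_genes = 2000, effect_size = 1,
                                 nb_dispersion = 40,
                                 lib_range = c(0.5, 1.5), seed = 1) {
  stopifnot(inherits(signatures, "signature_set"))
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (!all(c("sample_id", "arm", "day", "program") %in% names(design)))
    stop("design needs sample_id, arm, day, program columns")
  up <- signatures$up_genes; dn <- signatures$down_genes
  n_bg <- n_genes - length(up) - length(dn)
  if (n_bg < 0) stop("n_genes smaller than the signature sets")
  genes <- c(up, dn, sprintf("BG%05d", seq_len(n_bg)))
  beta <- c(rep(effect_size, length(up)), rep(-effect_size, length(dn)),
            rep(0, n_bg))
  set.seed(seed)
  baseline <- exp(stats::rnorm(n_genes, log(100), 1))
  lib_factor <- stats::runif(nrow(design), lib_range[1], lib_range[2])
  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    mu <- lib_factor[s] * baseline * 2^(beta * design$program[s])
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = nb_dispersion)
  }
  truth <- data.frame(gene = genes,
                      class = c(rep("up", length(up)),
                                rep("down", length(dn)),
                                rep("background", n_bg)),
                      beta = beta, baseline = baseline,
                      stringsAsFactors = FALSE)
  list(es = expr_set(counts, design), truth = truth)
}
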