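# Generative model for CyTOF-like event tables: per-cell latent exhaustion (e)
# and memory (m) programs drawn Beta around arm/day means; marker ion counts
# lognormal in the programs with zero inflation (dropout). Terminal-day cells
# carry a sub-mode label (1..4) encoding heterogeneity within the exhausted
# and memory fates.

#' Define a marker channel of the synthetic panel
#'
#' @param marker Channel label (unique within a panel).
#' @param baseline Log-intensity baseline (natural-log ion-count units).
#' @param load_e,load_m Loadings of the latent exhaustion / memory program on
#'   the log-intensity. Must be finite.
#' @param sigma Lognormal noise SD (log units), `>= 0`.
#' @param dropout Zero-inflation probability in `[0, 1)`.
#' @param role One of `"gate"`, `"exhaustion"`, `"memory"`, `"other"`.
#' @return One-row data frame usable as a panel row.
#' @export
marker_model <- function(marker, baseline, load_e = 0, load_m = 0,
                         sigma = 0.3, dropout = 0.1, role = "other") {
  if (!is.finite(load_e) || !is.finite(load_m))
    stop("non-finite loading for marker '", marker, "'")
  if (sigma < 0) stop("sigma must be >= 0 for marker '", marker, "'")
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1) for marker '", marker, "'")
  role <- match.arg(role, c("gate", "exhaustion", "memory", "other"))
  data.frame(marker = marker, baseline = baseline, load_e = load_e,
             load_m = load_m, sigma = sigma, dropout = dropout, role = role,
             stringsAsFactors = FALSE)
}

#' Default 22-channel synthetic marker panel
#'
#' Seven exhaustion-score markers (PD1, TIM3, LAG3, CTLA4, BTLA, 2B4, CD39),
#' four memory-score markers (CD45RA, IL7R, CD27, CD197), three gating
#' channels (CAR, CD8, CD4) and eight context markers, for 22 channels in
#' total. Own-panel program loadings are in natural-log units per unit
#' program, so a full program excursion spans several arcsinh units — the
#' dynamic range over which inhibitory-receptor and memory channels move
#' between negative and bright populations.
#'
#' @param sigma Lognormal noise SD shared by all channels.
#' @param dropout Zero-inflation probability shared by all channels.
#' @param load Own-panel program loading for score markers (natural-log
#'   units per unit program; 8 spans the upper end of the CyTOF
#'   inhibitory-receptor dynamic range).
#' @param context_load Program loading of the exhaustion/memory-linked
#'   context markers (TBET, BLIMP1, CD69, HLA-DR, CD57 on the exhaustion
#'   side; TCF1, CD62L on the memory side).
#' @return Data frame with one row per channel (see [marker_model()]).
#' @export
default_marker_panel <- function(sigma = 0.3, dropout = 0.1, load = 8,
                                 context_load = 5) {
  exh <- c("PD1", "TIM3", "LAG3", "CTLA4", "BTLA", "2B4", "CD39")
  mem <- c("CD45RA", "IL7R", "CD27", "CD197")
  rows <- list()
  for (mk in exh)
    rows[[mk]] <- marker_model(mk, baseline = 2.0, load_e = load,
                               sigma = sigma, dropout = dropout,
                               role = "exhaustion")
  for (mk in mem)
    rows[[mk]] <- marker_model(mk, baseline = 2.0, load_m = load,
                               sigma = sigma, dropout = dropout,
                               role = "memory")
  for (mk in c("CAR", "CD8", "CD4"))
    rows[[mk]] <- marker_model(mk, baseline = 3.0, sigma = sigma,
                               dropout = 0, role = "gate")
  # context markers: exhaustion-linked effector/activation markers and
  # memory-linked stemness markers carry the programs redundantly, as in
  # real panels where TFs and activation markers track the same biology
  rows[["TBET"]]   <- marker_model("TBET",   2.2, load_e = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["BLIMP1"]] <- marker_model("BLIMP1", 2.0, load_e = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["TCF1"]]   <- marker_model("TCF1",   2.0, load_m = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["CD62L"]]  <- marker_model("CD62L",  2.2, load_m = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["CD69"]]   <- marker_model("CD69",   2.4, load_e = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["HLADR"]]  <- marker_model("HLADR",  2.0, load_e = context_load,
                                   sigma = sigma, dropout = dropout)
  rows[["KI67"]]   <- marker_model("KI67",   2.1, sigma = sigma,
                                   dropout = dropout)
  rows[["CD57"]]   <- marker_model("CD57",   1.8, load_e = context_load,
                                   sigma = sigma, dropout = dropout)
  do.call(rbind, rows[c(exh, mem, "CAR", "CD8", "CD4", "TBET", "BLIMP1",
                        "TCF1", "CD62L", "CD69", "HLADR", "KI67", "CD57")])
}

#' Define an arm's latent-program trajectory
#'
#' @param arm Arm label, e.g. `"ALWAYS_ON"`.
#' @param day_grid Strictly increasing integer days.
#' @param mu_e,mu_m Per-day population means of the exhaustion / memory
#'   program, each strictly inside `(0, 1)`.
#' @param kappa Concentration of the per-cell Beta draw around the mean
#'   (`> 0`); larger values give tighter populations. Pre-terminal days
#'   only: terminal-day cells concentrate around sub-mode attractors.
#' @param submode_probs Length-4 probabilities with which terminal-day cells
#'   of this arm are assigned sub-modes 1..4.
#' @return A list of class `arm_trajectory`.
#' @export
arm_trajectory <- function(arm, day_grid, mu_e, mu_m, kappa = 6,
                           submode_probs = rep(0.25, 4)) {
  stopifnot(length(day_grid) >= 1, length(mu_e) == length(day_grid),
            length(mu_m) == length(day_grid))
  if (any(diff(day_grid) <= 0)) stop("day_grid must be strictly increasing")
  if (any(mu_e <= 0 | mu_e >= 1 | mu_m <= 0 | mu_m >= 1))
    stop("mu_e and mu_m must lie strictly inside (0, 1)")
  if (kappa <= 0) stop("kappa must be > 0")
  if (length(submode_probs) != 4 || any(submode_probs < 0))
    stop("submode_probs must be 4 nonnegative values")
  structure(list(arm = arm, day_grid = as.integer(day_grid),
                 mu_e = mu_e, mu_m = mu_m, kappa = kappa,
                 submode_probs = submode_probs / sum(submode_probs)),
            class = "arm_trajectory")
}

#' Default arm trajectories: continuous tonic signaling vs rest from day 7
#'
#' `ALWAYS_ON` drifts upward in the exhaustion program by 0.30 over days
#' 1-11; `RESTED_D7_11` tracks it to day 7 and then reverses while its
#' memory program rises by 0.30. Terminal-day sub-modes are biased toward the
#' exhausted pair (1, 2) for `ALWAYS_ON` and the memory pair (3, 4) for
#' `RESTED_D7_11`.
#'
#' @param kappa Beta concentration shared by both arms.
#' @return List of two [arm_trajectory()] objects.
#' @export
default_arm_trajectories <- function(kappa = 6) {
  list(
    arm_trajectory("ALWAYS_ON", c(1, 7, 9, 11),
                   mu_e = c(0.35, 0.50, 0.58, 0.65),
                   mu_m = c(0.40, 0.35, 0.32, 0.30),
                   kappa = kappa,
                   submode_probs = c(0.45, 0.45, 0.05, 0.05)),
    arm_trajectory("RESTED_D7_11", c(1, 7, 9, 11),
                   mu_e = c(0.35, 0.50, 0.42, 0.35),
                   mu_m = c(0.40, 0.38, 0.52, 0.70),
                   kappa = kappa,
                   submode_probs = c(0.05, 0.05, 0.45, 0.45))
  )
}

#' Default terminal-day sub-mode definitions
#'
#' On each arm's terminal day, cells have committed to one of four fate
#' attractors: two exhausted sub-modes (1 is CD39-high with the highest
#' exhaustion program) and two memory sub-modes (4 is IL7R/CD45RA-high with
#' the highest memory program). Each sub-mode is an absolute `(e, m)`
#' attractor around which terminal cells concentrate much more tightly than
#' the broad pre-terminal populations — the modal structure the terminal-day
#' regions formalize.
#'
#' @return Data frame with columns `submode`, `e_center`, `m_center`
#'   (attractor positions in `[0, 1]`) and a list-column `offsets` of named
#'   per-marker log-intensity offsets.
#' @export
default_submodes <- function() {
  out <- data.frame(submode = 1:4,
                    e_center = c(0.90, 0.52, 0.32, 0.12),
                    m_center = c(0.10, 0.28, 0.52, 0.90))
  out$offsets <- list(c(CD39 = 3), numeric(0), numeric(0),
                      c(IL7R = 3, CD45RA = 3))
  out
}

#' Sub-modes with no latent or marker structure
#'
#' For null scenarios: four indistinguishable terminal sub-modes centered
#' mid-range with no marker offsets, so a zero-loading panel yields truly
#' signal-free intensities.
#' @return Data frame in the format of [default_submodes()].
#' @export
null_submodes <- function() {
  out <- data.frame(submode = 1:4, e_center = 0.5, m_center = 0.5)
  out$offsets <- list(numeric(0), numeric(0), numeric(0), numeric(0))
  out
}

#' Assemble a cytometry simulation configuration
#'
#' @param n_cells_per_arm_day Cells simulated per arm per day (`>= 1`).
#' @param seed Integer random seed; a fixed seed gives bit-identical output.
#' @param marker_panel Panel data frame, see [default_marker_panel()].
#' @param arms List of [arm_trajectory()] objects.
#' @param submodes Sub-mode table, see [default_submodes()].
#' @param terminal_kappa Beta concentration of terminal-day cells around
#'   their sub-mode attractor (tighter than the pre-terminal `kappa`,
#'   reflecting fate commitment).
#' @param gate_pos_prob Named probabilities that a cell is positive for each
#'   gating channel (CD4 positivity is the complement of CD8).
#' @param gate_neg_shift Log-intensity decrement applied to gate-negative
#'   cells.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_arm_day = 1000, seed = 1,
                       marker_panel = default_marker_panel(),
                       arms = default_arm_trajectories(),
                       submodes = default_submodes(),
                       terminal_kappa = 80,
                       gate_pos_prob = c(CAR = 0.92, CD8 = 0.90),
                       gate_neg_shift = 2.5) {
  if (n_cells_per_arm_day < 1) stop("n_cells_per_arm_day must be >= 1")
  if (anyDuplicated(marker_panel$marker))
    stop("duplicated marker name in panel")
  required <- c("CAR", "CD8", "CD4", "PD1", "TIM3", "LAG3", "CTLA4", "BTLA",
                "2B4", "CD39", "CD45RA", "IL7R", "CD27", "CD197")
  missing <- setdiff(required, marker_panel$marker)
  if (length(missing))
    stop("marker panel is missing required channel(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(marker_panel$load_e)) ||
      any(!is.finite(marker_panel$load_m)))
    stop("non-finite loadings in marker panel")
  if (terminal_kappa <= 0) stop("terminal_kappa must be > 0")
  structure(list(n_cells_per_arm_day = as.integer(n_cells_per_arm_day),
                 seed = as.integer(seed), marker_panel = marker_panel,
                 arms = arms, submodes = submodes,
                 terminal_kappa = terminal_kappa,
                 gate_pos_prob = gate_pos_prob,
                 gate_neg_shift = gate_neg_shift),
            class = "sim_config")
}

#' Simulate a mass-cytometry event table with known latent truth
#'
#' For every arm and day, per-cell program weights `e` and `m` are drawn
#' `Beta(mu * kappa, (1 - mu) * kappa)` around the arm's day means. On each
#' arm's terminal day a sub-mode (1..4) is drawn and its latent shifts and
#' per-marker offsets applied. The raw intensity of marker j in cell i is 0
#' with probability `dropout_j`, otherwise lognormal with log-mean
#' `baseline_j + load_e_j * e_i + load_m_j * m_i (+ offset)` and log-SD
#' `sigma_j`. Gating channels are bimodal: gate-negative cells have their
#' log-mean lowered by `gate_neg_shift`.
#'
#' @param config A [sim_config()].
#' @return List with `events` (an untransformed [event_table()]) and `truth`
#'   (data frame `cell_id`, `arm`, `day`, `e`, `m`, `submode`; `submode` is
#'   `NA` off the terminal day).
#' @export
simulate_cytometry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$marker_panel
  n <- config$n_cells_per_arm_day
  meta <- list(); latent <- list()
  for (tr in config$arms) {
    terminal <- max(tr$day_grid)
    for (di in seq_along(tr$day_grid)) {
      day <- tr$day_grid[di]
      submode <- rep(NA_integer_, n)
      if (day == terminal) {
        # terminal-day cells commit to sub-mode attractors
        submode <- sample.int(4, n, replace = TRUE,
                              prob = tr$submode_probs)
        kt <- config$terminal_kappa
        ec <- config$submodes$e_center[submode]
        mc <- config$submodes$m_center[submode]
        e <- stats::rbeta(n, ec * kt, (1 - ec) * kt)
        m <- stats::rbeta(n, mc * kt, (1 - mc) * kt)
      } else {
        e <- stats::rbeta(n, tr$mu_e[di] * tr$kappa,
                          (1 - tr$mu_e[di]) * tr$kappa)
        m <- stats::rbeta(n, tr$mu_m[di] * tr$kappa,
                          (1 - tr$mu_m[di]) * tr$kappa)
      }
      cell_id <- sprintf("%s_D%02d_%05d", tr$arm, day, seq_len(n))
      meta[[length(meta) + 1L]] <-
        data.frame(cell_id = cell_id,
                   sample = sprintf("%s_D%02d", tr$arm, day),
                   arm = tr$arm, day = day, stringsAsFactors = FALSE)
      latent[[length(latent) + 1L]] <-
        data.frame(cell_id = cell_id, arm = tr$arm, day = day,
                   e = e, m = m, submode = submode,
                   stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, latent)
  ncell <- nrow(meta)

  # gate positivity indicators (CD4 complements CD8)
  gate_pos <- matrix(TRUE, ncell, 3,
                     dimnames = list(NULL, c("CAR", "CD8", "CD4")))
  gate_pos[, "CAR"] <- stats::runif(ncell) < config$gate_pos_prob[["CAR"]]
  gate_pos[, "CD8"] <- stats::runif(ncell) < config$gate_pos_prob[["CD8"]]
  gate_pos[, "CD4"] <- !gate_pos[, "CD8"]

  # per-terminal-cell marker offsets from sub-modes
  X <- matrix(0, ncell, nrow(panel), dimnames = list(NULL, panel$marker))
  offs <- matrix(0, ncell, nrow(panel), dimnames = list(NULL, panel$marker))
  idx_sub <- which(!is.na(truth$submode))
  for (s in 1:4) {
    o <- config$submodes$offsets[[s]]
    if (!length(o)) next
    rows <- idx_sub[truth$submode[idx_sub] == s]
    for (mk in names(o)) {
      if (!mk %in% panel$marker)
        stop("submode offset names unknown marker '", mk, "'")
      offs[rows, mk] <- offs[rows, mk] + o[[mk]]
    }
  }
  for (j in seq_len(nrow(panel))) {
    pj <- panel[j, ]
    log_mu <- pj$baseline + pj$load_e * truth$e + pj$load_m * truth$m +
      offs[, j]
    if (pj$role == "gate")
      log_mu <- log_mu - ifelse(gate_pos[, pj$marker], 0,
                                config$gate_neg_shift)
    x <- exp(stats::rnorm(ncell, log_mu, pj$sigma))
    if (pj$dropout > 0)
      x[stats::runif(ncell) < pj$dropout] <- 0
    X[, j] <- x
  }
  events <- event_table(cbind(meta, as.data.frame(X, check.names = FALSE)),
                        channels = panel$marker)
  list(events = events, truth = truth)
}
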