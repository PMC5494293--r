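#' Simulation configuration for synthetic Cq panels
#'
#' The generator emulates the structure of a biofluid qPCR miRNA panel:
#' per-miRNA baseline Cq levels drawn uniformly from
#' \code{baseline_range}, per-sample loading offsets (Normal, SD
#' \code{sample_offset_sd}), additive group effects of
#' \code{effect_cycles} cycles on a spiked subset (negative shift =
#' up-regulated, since lower Cq means higher abundance), Gaussian replicate
#' noise, designed reference probes with zero group effect and reduced
#' noise, and right-censoring at \code{censor_at} cycles (censored cells
#' are undetected, not truncated).
#'
#' Defaults describe a realistic gingival-crevicular-fluid panel: 600
#' assays, 6 healthy vs 6 periodontitis samples, baselines on (20, 37)
#' cycles so a tail of assays sits near the 40-cycle detection limit,
#' 1-cycle loading variation, 0.5-cycle replicate noise, 2-cycle effects on
#' 20 up- and 20 down-regulated miRNAs, and 5 reference probes.
#'
#' @param n_mirna total miRNAs on the panel.
#' @param n_healthy,n_perio samples per group.
#' @param baseline_range (low, high) cycles for per-miRNA baselines.
#' @param sample_offset_sd SD (cycles) of the per-sample loading offset.
#' @param noise_sd SD (cycles) of replicate noise.
#' @param n_up,n_down numbers of spiked up-/down-regulated miRNAs.
#' @param effect_cycles group-effect magnitude delta in cycles (>= 0): a
#'   single value applied to every spiked miRNA, or a length-2 range
#'   \code{c(low, high)} from which per-miRNA magnitudes are drawn
#'   uniformly (heterogeneous panels, as real biomarker panels are).
#' @param n_refs number of designed reference probes.
#' @param ref_noise_sd replicate-noise SD for reference probes.
#' @param censor_at detection limit in cycles.
#' @param set_id sample-set label for the emitted sample sheet.
#' @param seed RNG seed.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_mirna = 600, n_healthy = 6, n_perio = 6,
                       baseline_range = c(20, 37), sample_offset_sd = 1.0,
                       noise_sd = 0.5, n_up = 20, n_down = 20,
                       effect_cycles = 2.0, n_refs = 5, ref_noise_sd = 0.1,
                       censor_at = 40, set_id = "set1", seed = 1) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_healthy = as.integer(n_healthy),
              n_perio = as.integer(n_perio),
              baseline_range = as.numeric(baseline_range),
              sample_offset_sd = as.numeric(sample_offset_sd),
              noise_sd = as.numeric(noise_sd), n_up = as.integer(n_up),
              n_down = as.integer(n_down),
              effect_cycles = as.numeric(effect_cycles),
              n_refs = as.integer(n_refs),
              ref_noise_sd = as.numeric(ref_noise_sd),
              censor_at = as.numeric(censor_at),
              set_id = as.character(set_id)[1], seed = as.integer(seed))
  with(cfg, {
    if (n_mirna < 1 || n_healthy < 1 || n_perio < 1)
      stop("n_mirna, n_healthy, n_perio must be positive")
    if (n_up + n_down + n_refs > n_mirna)
      stop("n_up + n_down + n_refs exceeds n_mirna")
    if (length(baseline_range) != 2 || baseline_range[1] >= baseline_range[2])
      stop("baseline_range must be (low, high) with low < high")
    if (sample_offset_sd < 0 || noise_sd < 0 || ref_noise_sd < 0)
      stop("SDs must be >= 0")
    if (!length(effect_cycles) %in% 1:2 || any(effect_cycles < 0))
      stop("effect_cycles must be a value or (low, high) range, >= 0")
    if (length(effect_cycles) == 2 && effect_cycles[1] > effect_cycles[2])
      stop("effect_cycles range must have low <= high")
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic Cq dataset with known truth
#'
#' Model: Cq(i, s) = B_i + o_s + beta_i * [s in periodontitis] + eps(i, s),
#' where beta_i = -delta for spiked-up miRNAs (lower Cq = higher
#' expression), +delta for spiked-down, 0 otherwise; eps ~ Normal(0,
#' noise_sd^2), with \code{ref_noise_sd} for the designed reference probes.
#' Reference baselines are drawn from the middle of the baseline range so
#' they stay clear of the detection limit. Values at or above
#' \code{censor_at} become undetected. Bit-identical for a fixed seed.
#'
#' Passing the \code{truth} of a previous run reuses its baselines, spiked
#' assignments and per-miRNA effects and draws only fresh subjects, loading
#' offsets and noise — two such runs are independent sample sets drawn from
#' the same underlying truth, as in a discovery/validation design.
#'
#' @param config \code{sim_config}.
#' @param truth optional truth from an earlier \code{generate_cq_dataset}
#'   call with a compatible \code{n_mirna}.
#' @return list with \code{table} (\code{cq_table}), \code{sheet}
#'   (\code{sample_sheet}) and \code{truth} (spiked/reference
#'   \code{mirna_list}s, per-sample offsets, per-miRNA baselines and
#'   effects).
#' @export
generate_cq_dataset <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  c_ <- config
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(c_$seed)

  n_s <- c_$n_healthy + c_$n_perio
  mirna_ids <- sprintf("hsa-miR-sim-%04d", seq_len(c_$n_mirna))
  sample_ids <- c(sprintf("H%d", seq_len(c_$n_healthy)),
                  sprintf("P%d", seq_len(c_$n_perio)))
  grp <- rep(GROUP_LEVELS, c(c_$n_healthy, c_$n_perio))

  if (!is.null(truth)) {
    if (length(truth$baselines) != c_$n_mirna)
      stop("truth has ", length(truth$baselines), " miRNAs; config expects ",
           c_$n_mirna)
    mirna_ids <- names(truth$baselines)
    canon <- canonical_mirna(mirna_ids)
    role <- rep("null", c_$n_mirna)
    role[canon %in% truth$designed_refs$members] <- "ref"
    role[canon %in% truth$spiked_up$members] <- "up"
    role[canon %in% truth$spiked_down$members] <- "down"
    baselines <- unname(truth$baselines)
    beta <- unname(truth$effects)
  } else {
    role <- rep("null", c_$n_mirna)
    if (c_$n_refs > 0) role[seq_len(c_$n_refs)] <- "ref"
    if (c_$n_up > 0) role[c_$n_refs + seq_len(c_$n_up)] <- "up"
    if (c_$n_down > 0) role[c_$n_refs + c_$n_up + seq_len(c_$n_down)] <- "down"
    baselines <- stats::runif(c_$n_mirna, c_$baseline_range[1],
                              c_$baseline_range[2])
    mid <- mean(c_$baseline_range)
    span <- diff(c_$baseline_range) / 4
    baselines[role == "ref"] <- stats::runif(sum(role == "ref"),
                                             mid - span, mid + span)
    spiked <- role %in% c("up", "down")
    magnitude <- numeric(c_$n_mirna)
    magnitude[spiked] <- if (length(c_$effect_cycles) == 1) c_$effect_cycles
      else stats::runif(sum(spiked), c_$effect_cycles[1], c_$effect_cycles[2])
    beta <- ifelse(role == "up", -magnitude,
                   ifelse(role == "down", magnitude, 0))
  }
  offsets <- stats::rnorm(n_s, 0, c_$sample_offset_sd)
  noise_sd_i <- ifelse(role == "ref", c_$ref_noise_sd, c_$noise_sd)
  eps <- matrix(stats::rnorm(c_$n_mirna * n_s), c_$n_mirna, n_s) * noise_sd_i

  cq <- outer(baselines, offsets, "+") +
    outer(beta, as.numeric(grp == "periodontitis")) + eps
  cq[cq >= c_$censor_at] <- NA_real_
  cq[cq <= 0] <- NA_real_
  dimnames(cq) <- list(mirna_ids, sample_ids)

  ages <- ifelse(grp == "healthy",
                 round(stats::runif(n_s, 25, 55)), round(stats::runif(n_s, 35, 80)))
  gender <- sample(c("M", "F"), n_s, replace = TRUE)
  sheet <- sample_sheet(data.frame(
    sample_id = sample_ids, group = grp, set_id = c_$set_id,
    age = as.integer(ages), gender = gender,
    diagnosis = ifelse(grp == "healthy", "H", "CP"),
    stringsAsFactors = FALSE))

  truth <- list(spiked_up = mirna_list(mirna_ids[role == "up"], "spiked_up"),
                spiked_down = mirna_list(mirna_ids[role == "down"], "spiked_down"),
                designed_refs = mirna_list(mirna_ids[role == "ref"], "designed_refs"),
                offsets = stats::setNames(offsets, sample_ids),
                baselines = stats::setNames(baselines, mirna_ids),
                effects = stats::setNames(beta, mirna_ids))
  list(table = cq_table(cq, panel_id = "synthetic", censor_at = c_$censor_at),
       sheet = sheet, truth = truth)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Score recovery of simulated truth
#'
#' Confusion-based metrics for pipeline output against the generator's
#' ground truth: sensitivity and precision for the up and down lists
#' (precision is \code{NA} when a list is empty) and, optionally, how many
#' designed reference probes a stability ranking recovered.
#'
#' @param truth truth component of \code{generate_cq_dataset} output.
#' @param up,down \code{mirna_list}s from a pipeline run.
#' @param refs optional \code{mirna_list} of selected references.
#' @return list of metrics.
#' @export
score_recovery <- function(truth, up, down, refs = NULL) {
  upm <- if (inherits(up, "mirna_list")) up$members else canonical_mirna(up)
  dnm <- if (inherits(down, "mirna_list")) down$members else canonical_mirna(down)
  tu <- truth$spiked_up$members; td <- truth$spiked_down$members
  out <- list(
    up_sensitivity = safe_div(length(intersect(upm, tu)), length(tu)),
    up_precision = safe_div(length(intersect(upm, tu)), length(upm)),
    down_sensitivity = safe_div(length(intersect(dnm, td)), length(td)),
    down_precision = safe_div(length(intersect(dnm, td)), length(dnm)),
    n_false_up = length(setdiff(upm, tu)),
    n_false_down = length(setdiff(dnm, td)))
  if (!is.null(refs)) {
    rm_ <- if (inherits(refs, "mirna_list")) refs$members else canonical_mirna(refs)
    out$refs_recovered <- length(intersect(rm_, truth$designed_refs$members))
  }
  out
}
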