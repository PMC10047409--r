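#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-sample dCt = mean(Ct target) - mean(Ct reference),
#' ddCt = dCt - mean dCt of the calibrator group, and RQ = 2^-ddCt. The
#' calibrator group's geometric-mean RQ is 1 by construction, and adding a
#' constant to every Ct leaves RQ unchanged.
#'
#' @param data long-format data.frame with columns `sample`, `group`,
#'   `gene`, `role` (`target` or `reference`) and `ct`; one row per Ct
#'   replicate. Each sample needs at least one target and one reference
#'   replicate.
#' @param calibrator calibrator group label (e.g. the earliest stage).
#' @return list with `samples` (per-sample `dct`, `ddct`, `rq`) and
#'   `groups` (per-group mean and SD of RQ).
#' @export
ddct <- function(data, calibrator) {
  need <- c("sample", "group", "gene", "role", "ct")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (!calibrator %in% data$group)
    stop("calibrator group not present: ", calibrator)
  if (!all(data$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'")
  if (any(data$ct <= 0 | data$ct >= 45))
    stop("Ct values must lie in (0, 45)")

  per_sample <- lapply(split(data, data$sample), function(d) {
    ct_t <- d$ct[d$role == "target"]
    ct_r <- d$ct[d$role == "reference"]
    if (!length(ct_t) || !length(ct_r))
      stop("sample ", d$sample[1],
           " lacks target or reference Ct replicates")
    data.frame(sample = d$sample[1], group = d$group[1],
               dct = mean(ct_t) - mean(ct_r), stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, per_sample)
  rownames(samples) <- NULL
  cal_mean <- mean(samples$dct[samples$group == calibrator])
  samples$ddct <- samples$dct - cal_mean
  samples$rq <- 2^(-samples$ddct)

  groups <- do.call(rbind, lapply(split(samples, samples$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean_rq = mean(d$rq),
               sd_rq = stats::sd(d$rq), stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  list(samples = samples, groups = groups)
}

#' Dual-luciferase ratio normalization
#'
#' Computes the reporter ratio hluc / hRluc per well and normalizes each
#' construct's wells to the mean ratio of its negative-control treatment.
#' The ratio is invariant under a common rescaling of both channels.
#'
#' @param data data.frame with columns `construct`, `treatment`, `hluc`,
#'   `hrluc`; one row per well.
#' @param nc_label negative-control treatment label (default `"NC"`);
#'   required for every construct.
#' @return list with `wells` (per-well `ratio` and `activity`, the
#'   NC-normalized ratio) and `groups` (mean and SD of activity per
#'   construct x treatment).
#' @export
luc_ratio <- function(data, nc_label = "NC") {
  need <- c("construct", "treatment", "hluc", "hrluc")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  bad <- which(data$hrluc <= 0)
  if (length(bad))
    stop("hRluc must be positive; offending row(s): ",
         paste(bad, collapse = ", "))
  data$ratio <- data$hluc / data$hrluc

  wells <- do.call(rbind, lapply(split(data, data$construct), function(d) {
    nc <- d$ratio[d$treatment == nc_label]
    if (!length(nc))
      stop("construct ", d$construct[1], " has no '", nc_label,
           "' treatment")
    d$activity <- d$ratio / mean(nc)
    d
  }))
  rownames(wells) <- NULL
  groups <- do.call(rbind, lapply(
    split(wells, paste(wells$construct, wells$treatment, sep = "\r")),
    function(d) data.frame(construct = d$construct[1],
                           treatment = d$treatment[1], n = nrow(d),
                           mean_activity = mean(d$activity),
                           sd_activity = stats::sd(d$activity),
                           stringsAsFactors = FALSE)))
  groups <- groups[order(groups$construct, groups$treatment), ]
  rownames(groups) <- NULL
  list(wells = wells, groups = groups)
}
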