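## Event-record interchange format (NONMEM convention)
##
## Columns: id, time_h, evid (0 observation / 1 dose), amt (ug, dose rows),
## rate (ug/h, dose rows; rate > 0 encodes a zero-order infusion of duration
## amt/rate), dv (ug/L, observation rows), mdv, then covariate columns.

EVENT_COLUMNS <- c("id", "time_h", "evid", "amt", "rate", "dv", "mdv")

#' Write a cohort as an event-record CSV
#'
#' One dose row per infusion segment (`amt = rate * duration`, NONMEM
#' infusion convention) and one observation row per record; covariates are
#' repeated on every row of a subject. Times are written with 3-decimal
#' precision, concentrations at full precision.
#'
#' @param data A [population_dataset()].
#' @param path Output CSV path.
#' @param comment Optional header comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, comment = NULL) {
  stopifnot(inherits(data, "population_dataset"))
  cov_names <- unique(unlist(lapply(data$individuals, function(i)
    names(i$covariates))))
  rows <- lapply(data$individuals, function(ind) {
    reg <- ind$regimen
    n_d <- nrow(reg)
    n_o <- length(ind$times)
    df <- data.frame(
      id = rep(as.character(ind$id), n_d + n_o),
      time_h = round(c(reg$start_h, ind$times), 3),
      evid = c(rep(1L, n_d), rep(0L, n_o)),
      amt = c(reg$rate * (reg$end_h - reg$start_h), rep(NA_real_, n_o)),
      rate = c(reg$rate, rep(NA_real_, n_o)),
      dv = c(rep(NA_real_, n_d), ind$dv),
      mdv = c(rep(1L, n_d), rep(0L, n_o)),
      stringsAsFactors = FALSE)
    for (nm in cov_names)
      df[[nm]] <- if (is.null(ind$covariates[[nm]])) NA_real_
                  else ind$covariates[[nm]]
    df[order(df$time_h, -df$evid), ]
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an event-record CSV into a cohort
#'
#' Validates the schema, reconstructs infusion segments from `amt`/`rate`
#' pairs (duration `= amt/rate`), attaches per-subject covariates (taken
#' from each subject's first row), and optionally excludes observations
#' below the limit of quantification.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @param lloq If non-`NULL`, observations with `dv < lloq` are dropped
#'   (M1 below-LLOQ policy) and the count is reported via a message.
#' @return A [population_dataset()].
#' @export
read_dataset <- function(path, lloq = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  miss <- setdiff(EVENT_COLUMNS, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tab$time_h)))
    stop("non-numeric time_h at row(s) ",
         paste(which(!is.finite(tab$time_h)), collapse = ", "))
  if (any(tab$time_h < 0))
    stop("negative time_h at row(s) ",
         paste(which(tab$time_h < 0), collapse = ", "))
  if (!all(tab$evid %in% c(0L, 1L)))
    stop("evid must be 0 or 1 at row(s) ",
         paste(which(!tab$evid %in% c(0L, 1L)), collapse = ", "))
  bad_rate <- tab$evid == 1 &
    (!is.finite(tab$rate) | tab$rate <= 0 | !is.finite(tab$amt))
  if (any(bad_rate))
    stop("dose rows need amt and rate > 0; offending row(s) ",
         paste(which(bad_rate), collapse = ", "))
  bad_dv <- tab$evid == 0 & !is.finite(tab$dv)
  if (any(bad_dv))
    stop("observation rows need dv; offending row(s) ",
         paste(which(bad_dv), collapse = ", "))
  cov_names <- setdiff(names(tab), EVENT_COLUMNS)
  n_blq <- 0L
  inds <- list()
  for (id in unique(tab$id)) {
    sub <- tab[tab$id == id, , drop = FALSE]
    if (is.unsorted(sub$time_h))
      stop("times not sorted within subject ", id)
    dose <- sub[sub$evid == 1, , drop = FALSE]
    obs <- sub[sub$evid == 0, , drop = FALSE]
    if (!is.null(lloq)) {
      drop <- obs$dv < lloq
      n_blq <- n_blq + sum(drop)
      obs <- obs[!drop, , drop = FALSE]
    }
    reg <- infusion_regimen(dose$time_h, dose$time_h + dose$amt / dose$rate,
                            dose$rate)
    covs <- as.list(sub[1, cov_names, drop = FALSE])
    covs <- covs[!vapply(covs, function(x) is.null(x) || is.na(x), TRUE)]
    inds[[length(inds) + 1L]] <-
      individual_data(id = id, regimen = reg, times = obs$time_h,
                      dv = obs$dv, covariates = do.call(covariate_set, covs))
  }
  if (n_blq > 0)
    message(n_blq, " observation(s) below LLOQ excluded")
  population_dataset(inds)
}
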