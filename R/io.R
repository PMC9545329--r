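# Delimited-text readers/writers for datasets and posterior draws, plus the
# optional outcome standardization applied at read time.

#' Write a dataset to delimited text
#'
#' Two CSV files: a long-format longitudinal table
#' (`subject_id, outcome, time, value`) and a subject table
#' (`subject_id, intervention, <covariates...>, observed_time, event`).
#'
#' @param dataset list of [jm_subject()] records.
#' @param longitudinal_path,subject_path output CSV paths.
#' @return list of the written paths, invisibly.
#' @export
write_jm_data <- function(dataset, longitudinal_path, subject_path) {
  long <- do.call(rbind, lapply(dataset, function(s) {
    rbind(
      if (nrow(s$series1))
        data.frame(subject_id = s$id, outcome = 1L, time = s$series1$time,
                   value = s$series1$value),
      if (nrow(s$series2))
        data.frame(subject_id = s$id, outcome = 2L, time = s$series2$time,
                   value = s$series2$value))
  }))
  if (is.null(long))
    long <- data.frame(subject_id = character(0), outcome = integer(0),
                       time = numeric(0), value = numeric(0))
  subj <- do.call(rbind, lapply(dataset, function(s) {
    cov <- as.data.frame(as.list(s$covariates))
    base <- data.frame(subject_id = s$id, intervention = s$intervention)
    if (ncol(cov)) base <- cbind(base, cov)
    cbind(base, data.frame(observed_time = s$observed_time, event = s$event))
  }))
  write.csv(long, longitudinal_path, row.names = FALSE)
  write.csv(subj, subject_path, row.names = FALSE)
  invisible(list(longitudinal = longitudinal_path, subjects = subject_path))
}

#' Read a dataset from delimited text
#'
#' Validates the two tables (schema, duplicate measurement keys, orphan
#' subjects, measurements after the observed time) and assembles
#' [jm_subject()] records. Subjects without measurements are legal
#' (survival-only information).
#'
#' @param longitudinal_path,subject_path CSV paths as written by
#'   [write_jm_data()].
#' @param standardize scale each outcome to zero mean and unit variance using
#'   the mean and SD over all subjects and time points (as is done for real
#'   trial outcomes before fitting); off by default.
#' @return list of [jm_subject()] records; when `standardize = TRUE` the
#'   scaling constants are attached as attribute `"scaling"`.
#' @export
read_jm_data <- function(longitudinal_path, subject_path, standardize = FALSE) {
  long <- read.csv(longitudinal_path, stringsAsFactors = FALSE)
  subj <- read.csv(subject_path, stringsAsFactors = FALSE)
  need_l <- c("subject_id", "outcome", "time", "value")
  need_s <- c("subject_id", "intervention", "observed_time", "event")
  if (!all(need_l %in% names(long)))
    stop("longitudinal table must have columns: ", paste(need_l, collapse = ", "))
  if (!all(need_s %in% names(subj)))
    stop("subject table must have columns: ", paste(need_s, collapse = ", "))
  if (anyDuplicated(subj$subject_id))
    stop("duplicate subject_id in subject table: ",
         paste(unique(subj$subject_id[duplicated(subj$subject_id)]), collapse = ", "))
  if (nrow(long)) {
    if (!all(long$outcome %in% 1:2))
      stop("longitudinal outcome labels must be 1 or 2")
    key <- paste(long$subject_id, long$outcome, long$time)
    if (anyDuplicated(key))
      stop("duplicate (subject, outcome, time) measurement keys: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    orphan <- setdiff(long$subject_id, subj$subject_id)
    if (length(orphan))
      stop("longitudinal measurements for subjects absent from the subject table: ",
           paste(orphan, collapse = ", "))
  }
  scaling <- NULL
  if (standardize && nrow(long)) {
    scaling <- lapply(1:2, function(o) {
      v <- long$value[long$outcome == o]
      if (!length(v)) return(c(mean = 0, sd = 1))
      c(mean = mean(v), sd = if (sd(v) > 0) sd(v) else 1)
    })
    for (o in 1:2) {
      rows <- long$outcome == o
      long$value[rows] <- (long$value[rows] - scaling[[o]]["mean"]) /
        scaling[[o]]["sd"]
    }
  }
  covnames <- setdiff(names(subj), need_s)
  dataset <- lapply(seq_len(nrow(subj)), function(i) {
    row <- subj[i, ]
    rows <- long[long$subject_id == row$subject_id, , drop = FALSE]
    if (nrow(rows) && any(rows$time > row$observed_time + 1e-9))
      stop(sprintf("subject %s has a measurement after its observed time",
                   row$subject_id))
    pick <- function(o) {
      r <- rows[rows$outcome == o, c("time", "value"), drop = FALSE]
      r[order(r$time), , drop = FALSE]
    }
    jm_subject(id = as.character(row$subject_id),
               intervention = row$intervention,
               covariates = if (length(covnames))
                 unlist(row[covnames]) else numeric(0),
               series1 = pick(1), series2 = pick(2),
               observed_time = row$observed_time, event = row$event)
  })
  class(dataset) <- c("jm_dataset", "list")
  if (!is.null(scaling)) attr(dataset, "scaling") <- scaling
  dataset
}

#' Persist posterior draws as a flat table plus a JSON sidecar
#'
#' The table has columns `chain, iteration, parameter, value`; the sidecar
#' records the parameter order, model structure, baseline-spline knots and
#' MCMC settings so the draws can be reloaded with [read_jm_draws()].
#'
#' @param draws a `jm_draws` object.
#' @param path CSV path for the flat table.
#' @param meta_path JSON path (defaults to `path` with a `.json` extension).
#' @return list of written paths, invisibly.
#' @export
write_jm_draws <- function(draws, path, meta_path = sub("\\.csv$", ".json", path)) {
  stopifnot(inherits(draws, "jm_draws"))
  flat <- do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), times = ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  write.csv(flat, path, row.names = FALSE)
  model <- draws$model
  meta <- list(parameters = draws$parameters,
               univariate = is_univariate(model),
               long1_fixed = model$long1$fixed,
               long2_fixed = if (!is_univariate(model)) model$long2$fixed,
               survival_terms = model$survival_terms,
               baseline = draws$baseline_spec,
               n_subjects = draws$n_subjects,
               mcmc = unclass(draws$mcmc))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(draws = path, meta = meta_path))
}

#' Reload posterior draws written by [write_jm_draws()]
#'
#' @param path CSV path of the flat draws table.
#' @param meta_path JSON sidecar path.
#' @return a `jm_draws` object.
#' @export
read_jm_draws <- function(path, meta_path = sub("\\.csv$", ".json", path)) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  model <- jm_model(
    long1 = jm_longitudinal_spec(meta$long1_fixed),
    long2 = if (isTRUE(meta$univariate)) NULL else
      jm_longitudinal_spec(meta$long2_fixed, upstream = TRUE),
    survival_terms = meta$survival_terms)
  chains <- lapply(sort(unique(flat$chain)), function(ch) {
    d <- flat[flat$chain == ch, ]
    m <- sapply(meta$parameters, function(p)
      d$value[d$parameter == p][order(d$iteration[d$parameter == p])])
    matrix(m, ncol = length(meta$parameters),
           dimnames = list(NULL, meta$parameters))
  })
  structure(list(chains = chains, lp = NULL, model = model,
                 baseline_spec = meta$baseline,
                 parameters = meta$parameters, accept = NULL,
                 mcmc = do.call(jm_mcmc, meta$mcmc[c("n_iter", "n_burnin",
                                                     "n_chains", "thin")]),
                 n_subjects = meta$n_subjects),
            class = "jm_draws")
}
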