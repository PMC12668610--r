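#' Binding-site posterior tables
#'
#' Motif scanners of the SwissRegulon type return, per promoter, candidate
#' binding sites with a posterior probability each. A binding-site table has
#' one row per site: `promoter, tf, start, end, posterior`, with `tf` one of
#' Rgt1 (the DNA-binding factor through which Mth1/Std1 act), Mig1, or Mig2.
#'
#' @param x A data frame with those columns.
#' @return A validated tibble.
#' @export
as_binding_sites <- function(x) {
  need <- c("promoter", "tf", "start", "end", "posterior")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("binding-site table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  ok_tf <- c("Rgt1", "Mig1", "Mig2")
  idx <- match(tolower(x$tf), tolower(ok_tf))
  if (anyNA(idx)) rlang::abort("tf must be one of Rgt1, Mig1, Mig2")
  x$tf <- ok_tf[idx]
  if (any(x$posterior < 0 | x$posterior > 1)) {
    rlang::abort("site posteriors must lie in [0, 1]")
  }
  if (any(x$start <= 0 | x$end < x$start)) {
    rlang::abort("site coordinates must be positive with start <= end")
  }
  x
}

#' @rdname as_binding_sites
#' @param path TSV file with the same columns.
#' @export
read_binding_sites <- function(path) {
  as_binding_sites(utils::read.delim(path, check.names = FALSE))
}

#' Predicted promoter occupancy of a TF group
#'
#' In the low-concentration limit (TF concentration well below every site's
#' dissociation constant) occupancy is linear in site availability, so the
#' expected occupancy of a group of factors is simply the sum of its sites'
#' posterior probabilities. A complement form `1 - prod(1 - p)` — the
#' probability that at least one site exists — is available as an alternative
#' estimator.
#'
#' @param sites A binding-site table (see [as_binding_sites()]).
#' @param promoter Promoter name present in the table.
#' @param tf_group Character vector of TF names.
#' @param method `"sum"` (low-concentration limit, default) or
#'   `"complement"`.
#' @return Non-negative scalar.
#' @export
occupancy_score <- function(sites, promoter, tf_group,
                            method = c("sum", "complement")) {
  method <- match.arg(method)
  sites <- as_binding_sites(sites)
  if (!promoter %in% sites$promoter) {
    rlang::abort(paste0("unknown promoter: ", promoter))
  }
  p <- sites$posterior[sites$promoter == promoter &
    tolower(sites$tf) %in% tolower(tf_group)]
  if (length(p) == 0) return(0)
  switch(method,
    sum = sum(p),
    complement = 1 - prod(1 - p)
  )
}

#' Promoter bias between the two repressor pairs
#'
#' `log2((occupancy(Rgt1) + pseudocount) / (occupancy(Mig1, Mig2) +
#' pseudocount))`: positive means the promoter favours Mth1/Std1 binding (via
#' Rgt1), negative means it favours Mig1/Mig2. The pseudocount keeps the bias
#' finite when a group has no sites.
#'
#' @inheritParams occupancy_score
#' @param pseudocount Small positive scalar added to both occupancies.
#' @return Signed scalar.
#' @export
promoter_bias <- function(sites, promoter, pseudocount = 0.01,
                          method = c("sum", "complement")) {
  method <- match.arg(method)
  rgt1 <- occupancy_score(sites, promoter, "Rgt1", method)
  mig <- occupancy_score(sites, promoter, c("Mig1", "Mig2"), method)
  log2((rgt1 + pseudocount) / (mig + pseudocount))
}

#' Occupancy bias for every promoter in a table
#'
#' @inheritParams promoter_bias
#' @return Tibble: `promoter, occupancy_rgt1, occupancy_mig, bias`.
#' @export
occupancy_bias_table <- function(sites, pseudocount = 0.01,
                                 method = c("sum", "complement")) {
  method <- match.arg(method)
  sites <- as_binding_sites(sites)
  purrr::map_dfr(unique(sites$promoter), function(pr) {
    tibble::tibble(
      promoter = pr,
      occupancy_rgt1 = occupancy_score(sites, pr, "Rgt1", method),
      occupancy_mig = occupancy_score(sites, pr, c("Mig1", "Mig2"), method),
      bias = promoter_bias(sites, pr, pseudocount, method)
    )
  })
}
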