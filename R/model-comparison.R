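# Prior surgery (including/excluding parameters) and free-energy-based
# comparison of candidate connectivity structures.

#' Exclude a parameter from a model
#'
#' Sets the parameter's prior mean and variance to zero, which fixes it at
#' zero during inversion and removes it from the tunable subspace (the SPM
#' convention for absent connections).  Idempotent.
#'
#' @param prior A `dcm_prior`.
#' @param name Parameter name(s), e.g. `connection_name(1, 3)`.
#' @return Modified `dcm_prior`.
#' @export
exclude_parameter <- function(prior, name) {
  stopifnot(inherits(prior, "dcm_prior"))
  unknown <- setdiff(name, names(prior$mean))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  prior$mean[name] <- 0
  prior$var[name] <- 0
  prior$tunable[name] <- FALSE
  prior
}

#' Set the tunable flag of a parameter
#'
#' `flag = FALSE` freezes the parameter at its current (possibly nonzero)
#' prior mean without altering the mean -- a fixed effective connection that
#' remains unchanged during optimization.  `flag = TRUE` re-enables
#' optimization (the parameter must retain positive prior variance for this
#' to have an effect).
#'
#' @param prior A `dcm_prior`.
#' @param name Parameter name(s).
#' @param flag Logical.
#' @return Modified `dcm_prior`.
#' @export
set_tunable <- function(prior, name, flag) {
  stopifnot(inherits(prior, "dcm_prior"), is.logical(flag))
  unknown <- setdiff(name, names(prior$mean))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  prior$tunable[name] <- flag
  prior
}

#' Compare fitted models by free energy
#'
#' Tabulates the free energies of a set of inversions of the *same* data
#' and reports each model's free energy relative to a reference model
#' (`relative_F = F - F_reference`), sorted in decreasing order of F with
#' the best model flagged.  All posteriors must carry identical data
#' fingerprints; comparing fits of different data is refused.
#'
#' @param results Named list of `dcm_posterior` objects (names are model
#'   labels), or a list of `list(label =, posterior =)` pairs.
#' @param reference Label of the reference model (default: first element).
#' @return Data frame with columns `label`, `F`, `relative_F`, `best`.
#' @export
compare_free_energies <- function(results, reference = NULL) {
  if (!length(results)) stop("no results to compare")
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("`results` must be a named list of posteriors")
  }
  ok <- vapply(results, inherits, logical(1), what = "dcm_posterior")
  if (!all(ok)) stop("all results must be dcm_posterior objects")
  hashes <- vapply(results, function(r) r$data_hash, character(1))
  if (length(unique(hashes)) > 1) {
    stop("posteriors were fitted to different data (mismatched data hashes)")
  }
  if (is.null(reference)) reference <- names(results)[1]
  if (!reference %in% names(results)) {
    stop(sprintf("reference label '%s' not found", reference))
  }
  F <- vapply(results, function(r) r$F, numeric(1))
  out <- data.frame(label = names(results), F = unname(F),
                    relative_F = unname(F - F[[reference]]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$F), ]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}
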