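#' Center of mass of spatial expression profiles
#'
#' The expression-weighted mean zone index of a profile across zones
#' 1..N with per-zone expression E_1..E_N:
#' \deqn{COM = \sum_{i=1}^{N} E_i \, i \; / \; \sum_{i=1}^{N} E_i}
#' A flat profile has COM (N+1)/2; crypt-biased genes have COM near 1 and
#' tip-biased genes COM near N. An all-zero profile has no defined COM (NA).
#'
#' @param profile numeric vector of per-zone expression, or a genes x zones
#'   matrix (one COM per row)
#' @return scalar COM, or a named vector for matrix input
#' @export
center_of_mass <- function(profile) {
  if (is.matrix(profile)) {
    tot <- rowSums(profile)
    com <- as.vector(profile %*% seq_len(ncol(profile))) / tot
    com[tot == 0] <- NA_real_
    names(com) <- rownames(profile)
    return(com)
  }
  tot <- sum(profile)
  if (tot == 0) return(NA_real_)
  sum(profile * seq_along(profile)) / tot
}
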