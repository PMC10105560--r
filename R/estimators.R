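# The four parent-offspring-pair census-size estimators. The three
# count-based methods (CKMR, g-CMR, Moment) consume the kin_counts tallies;
# CRE works directly on the sampled pedigree. Degenerate samples (no POPs, no
# juveniles, ...) yield `defined = FALSE` rather than an error so that batch
# experiments can record the failure rate.

estimate_row <- function(method, target, n_hat) {
  defined <- is.finite(n_hat) && n_hat >= 0
  tibble(method = method, target = target,
         n_hat = if (defined) n_hat else NA_real_, defined = defined)
}

#' Naive close-kin mark-recapture (CKMR) estimate of adult abundance
#'
#' Lincoln-Petersen adaptation in which each sampled offspring "marks" its two
#' parents: with `n_juv` sampled juveniles, `n_adult` sampled adults and
#' `h_total` parent-offspring pairs observed between them (pairs among adults
#' included, as required when generations overlap), the adult population
#' estimate is
#' \deqn{\hat N_{adult} = 2\, n_{juv}\, n_{adult} / h_{total}.}
#'
#' @param counts One-row tibble from [kin_counts()].
#' @return One-row tibble: `method`, `target` (`"adult"`), `n_hat`, `defined`.
#'   `defined` is `FALSE` when `h_total`, `n_juv` or `n_adult` is zero.
#' @examples
#' estimate_ckmr(tibble::tibble(n_juv = 20, n_adult = 30, h_total = 40))
#' @export
estimate_ckmr <- function(counts) {
  if (counts$h_total == 0 || counts$n_juv == 0 || counts$n_adult == 0) {
    return(estimate_row("CKMR", "adult", NA_real_))
  }
  estimate_row("CKMR", "adult",
               2 * counts$n_juv * counts$n_adult / counts$h_total)
}

#' Genetic capture-mark-recapture (g-CMR) estimate of total abundance
#'
#' Per-sex Lincoln-Petersen on parentage: every sampled individual carries a
#' "mark" naming its mother and father, and a sampled adult of the right sex
#' is a recapture of that mark. With sample size `n`,
#' \deqn{\hat N_{f} = n\, n_{adult,f} / h_{mother}, \qquad
#'       \hat N_{m} = n\, n_{adult,m} / h_{father},}
#' the adult estimate is their sum and the total estimate inflates it by the
#' sampled adult fraction: \eqn{\hat N_{total} = (\hat N_f + \hat N_m)\,
#' (n / n_{adult})}, valid under uniform sampling.
#'
#' @param counts One-row tibble from [kin_counts()].
#' @return One-row tibble with `target = "total"`; `defined = FALSE` when
#'   `h_mother`, `h_father` or `n_adult` is zero.
#' @examples
#' estimate_gcmr(tibble::tibble(n = 100, n_adult = 50, n_adult_f = 30,
#'                              h_mother = 10, n_adult_m = 20, h_father = 5))
#' @export
estimate_gcmr <- function(counts) {
  if (counts$h_mother == 0 || counts$h_father == 0 || counts$n_adult == 0) {
    return(estimate_row("gCMR", "total", NA_real_))
  }
  n_f_hat <- counts$n * counts$n_adult_f / counts$h_mother
  n_m_hat <- counts$n * counts$n_adult_m / counts$h_father
  out <- estimate_row("gCMR", "total",
                      (n_f_hat + n_m_hat) * counts$n / counts$n_adult)
  out$n_hat_f <- if (out$defined) n_f_hat else NA_real_
  out$n_hat_m <- if (out$defined) n_m_hat else NA_real_
  out
}

#' Moment estimate of breeding-female abundance
#'
#' Method-of-moments estimator from mother-daughter pair frequency among
#' sampled females: each unordered pair of sampled females is a
#' mother-daughter pair with probability approximately `2 / N_F`, so with
#' `n_f` sampled females and `k_md` mother-daughter pairs,
#' \deqn{\hat N_{F} = n_f (n_f - 1) / k_{md}.}
#' Daughters of any age count, mirroring the adult-adult POP inclusion rule.
#'
#' @param counts One-row tibble from [kin_counts()].
#' @return One-row tibble with `target = "breeding_females"`;
#'   `defined = FALSE` when `k_md = 0` or `n_f < 2`.
#' @examples
#' estimate_moment(tibble::tibble(n_f = 11, k_md = 10))
#' @export
estimate_moment <- function(counts) {
  if (counts$k_md == 0 || counts$n_f < 2) {
    return(estimate_row("Moment", "breeding_females", NA_real_))
  }
  estimate_row("Moment", "breeding_females",
               counts$n_f * (counts$n_f - 1) / counts$k_md)
}

#' Creel-Rosenblatt estimate (CRE) of adult abundance
#'
#' Counts breeders directly from the reconstructed pedigree of the sample:
#' the sampled breeders `B_s` (distinct sampled individuals that are a parent
#' of at least one sampled individual) plus the inferred unsampled breeders
#' `B_u` (distinct unsampled individuals that are a parent of a sampled
#' individual whose other parent was sampled -- their presence is revealed by
#' the sampled mate and shared offspring). The estimate is `B_s + B_u`.
#'
#' @param sample A `kin_sample` from [draw_sample()].
#' @param pedigree The pedigree the sample was drawn from.
#' @return One-row tibble with `target = "adult"`; `defined = FALSE` when no
#'   breeder is detected at all.
#' @export
estimate_cre <- function(sample, pedigree) {
  rows <- match(sample$id, pedigree$id)
  mo <- pedigree$mother_id[rows]
  fa <- pedigree$father_id[rows]
  in_s <- function(ids) !is.na(ids) & ids %in% sample$id
  mo_in <- in_s(mo)
  fa_in <- in_s(fa)
  b_s <- unique(c(mo[mo_in], fa[fa_in]))
  # unsampled parent inferred through a sampled mate and a shared sampled child
  b_u <- unique(c(mo[!is.na(mo) & !mo_in & fa_in],
                  fa[!is.na(fa) & !fa_in & mo_in]))
  n_hat <- length(b_s) + length(b_u)
  if (n_hat == 0) return(estimate_row("CRE", "adult", NA_real_))
  estimate_row("CRE", "adult", n_hat)
}

#' Apply all four estimators to one sample
#'
#' Convenience fan-out: finds the POPs, tallies the kin counts and returns
#' one row per method, with the kin-count columns attached so downstream
#' summaries can condition on the observed number of POPs.
#'
#' @param sample A `kin_sample`.
#' @param pedigree The pedigree the sample was drawn from.
#' @return Four-row tibble: `method`, `target`, `n_hat`, `defined`, plus all
#'   [kin_counts()] columns repeated on each row.
#' @examples
#' ped <- simulate_pedigree(species_params("wild_boar"), n_years = 40, seed = 1)
#' estimate_all(draw_sample(ped, 0.3, seed = 9), ped)
#' @export
estimate_all <- function(sample, pedigree) {
  pops <- find_pops(sample, pedigree)
  counts <- kin_counts(sample, pops, pedigree)
  ests <- dplyr::bind_rows(
    estimate_ckmr(counts),
    estimate_gcmr(counts),
    estimate_moment(counts),
    estimate_cre(sample, pedigree)
  )
  dplyr::bind_cols(ests, counts[rep(1L, nrow(ests)), ])
}
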