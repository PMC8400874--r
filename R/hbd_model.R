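# The multiple-HBD-class model: C HBD age classes with exponential
# segment-length distributions (rates R_k per Morgan) plus one non-HBD class.
# The length of a class-k segment is Exp(R_k): the probability that a segment
# survives between two markers d Morgans apart is exp(-R_k d), and its expected
# length is 1/R_k Morgans. Small rates correspond to long segments from recent
# ancestors (R = 2 ~ parents), large rates to short, ancient segments.

#' Construct an HBD-class model
#'
#' @param rates positive, non-decreasing vector of exponential rates, one per
#'   HBD class followed by the non-HBD class (the last entry).
#' @param mixing vector on the simplex: the probability that a newly started
#'   segment belongs to each class ("class frequency").
#' @param eps genotyping error / mutation nuisance probability in \[0, 0.5):
#'   its essential role is to allow heterozygous calls inside HBD segments.
#' @return An object of class `hbd_model` with fields `rates`, `mixing`,
#'   `eps`, `n_states` and `state_names` (HBD classes named by their rate,
#'   e.g. `"R_2"`; the last state is `"nonHBD"`).
#' @export
hbd_model <- function(rates, mixing, eps = 0.001) {
  rates <- as.numeric(rates); mixing <- as.numeric(mixing)
  S <- length(rates)
  if (S < 2L) stop("need at least one HBD class plus the non-HBD class")
  if (any(rates <= 0)) stop("rates must be positive")
  if (any(diff(rates[-S]) < 0)) stop("HBD class rates must be non-decreasing")
  if (length(mixing) != S) stop("mixing must have one entry per state")
  if (any(mixing < 0) || abs(sum(mixing) - 1) > 1e-12)
    stop("mixing must be non-negative and sum to 1")
  if (!is.numeric(eps) || eps < 0 || eps >= 0.5)
    stop("eps must be in [0, 0.5)")
  state_names <- c(paste0("R_", format(rates[-S], trim = TRUE, scientific = FALSE)),
                   "nonHBD")
  structure(list(rates = rates, mixing = mixing, eps = eps,
                 n_states = S, state_names = state_names),
            class = "hbd_model")
}

#' @export
print.hbd_model <- function(x, ...) {
  cat("hbd_model:", x$n_states - 1L, "HBD classes + non-HBD, eps =", x$eps, "\n")
  tab <- rbind(rate = x$rates, mixing = signif(x$mixing, 4))
  colnames(tab) <- x$state_names
  print(tab)
  invisible(x)
}

#' Default HBD-class model
#'
#' The default ladder uses `n_classes - 1` HBD classes with rates
#' 2, 4, ..., 2^(n_classes-1) (so 2..512 for the default 10 states) and a
#' non-HBD class sharing the last HBD rate; mixing starts uniform.
#'
#' @param n_classes total number of states (HBD classes + 1 non-HBD), >= 2.
#' @param eps genotyping-error probability.
#' @return An [hbd_model()].
#' @export
default_model <- function(n_classes = 10, eps = 0.001) {
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("n_classes must be at least 2")
  C <- as.integer(n_classes) - 1L
  hbd_rates <- 2^seq_len(C)
  hbd_model(rates = c(hbd_rates, hbd_rates[C]),
            mixing = rep(1 / n_classes, n_classes), eps = eps)
}

#' Approximate ancestor age of an HBD class
#'
#' An HBD class with rate R gathers segments inherited from common ancestors
#' roughly R/2 generations back: R = 2 corresponds to parents, R = 4 to
#' grandparents, and so on.
#'
#' @param rate positive class rate (per Morgan).
#' @return `rate / 2`, the approximate number of generations to the ancestor.
#' @export
class_generation <- function(rate) {
  if (any(!is.numeric(rate)) || any(rate <= 0)) stop("rate must be positive")
  rate / 2
}

#' Expected HBD segment length of a class
#'
#' @param rate positive class rate (per Morgan).
#' @return `1 / rate`, the expected segment length in Morgans.
#' @export
expected_length <- function(rate) {
  if (any(!is.numeric(rate)) || any(rate <= 0)) stop("rate must be positive")
  1 / rate
}

#' Per-state genotype emission probabilities
#'
#' Within an HBD segment both chromosome copies descend from one ancestral
#' copy, so with coded-allele frequency p the genotype is homozygous for the
#' coded allele with probability p (and for the other allele with probability
#' 1-p), perturbed by the error rate eps which redistributes mass to
#' Hardy-Weinberg proportions:
#' \deqn{P(2|HBD) = (1-\epsilon)p + \epsilon p^2,\;
#'       P(1|HBD) = \epsilon\, 2p(1-p),\;
#'       P(0|HBD) = (1-\epsilon)(1-p) + \epsilon (1-p)^2.}
#' The non-HBD state emits pure Hardy-Weinberg proportions
#' \eqn{p^2, 2p(1-p), (1-p)^2}. A missing genotype has likelihood 1 in every
#' state. All HBD classes share one emission distribution.
#'
#' @param g genotype in \{0, 1, 2\} or `NA` (missing).
#' @param p coded-allele frequency in \[0, 1\].
#' @param eps genotyping-error probability.
#' @param n_states total number of states (HBD classes first, non-HBD last).
#' @return Numeric vector of length `n_states` of emission likelihoods.
#' @export
emission_probs <- function(g, p, eps = 0.001, n_states = 10) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("allele frequency must be in [0, 1]")
  if (is.na(g)) return(rep(1, n_states))
  if (!g %in% c(0, 1, 2)) stop("genotype must be 0, 1, 2 or missing")
  q <- 1 - p
  hbd <- switch(as.character(g),
                "2" = (1 - eps) * p + eps * p^2,
                "1" = eps * 2 * p * q,
                "0" = (1 - eps) * q + eps * q^2)
  non <- switch(as.character(g), "2" = p^2, "1" = 2 * p * q, "0" = q^2)
  c(rep(hbd, n_states - 1L), non)
}

# Emission likelihood matrix for one individual: markers x states.
# Missing genotypes get likelihood 1; entries floored at 1e-300.
emission_matrix <- function(genotypes, p, model) {
  stopifnot(length(genotypes) == length(p))
  if (any(p < 0 | p > 1)) stop("allele frequencies must be in [0, 1]")
  eps <- model$eps; q <- 1 - p
  hbd <- rep(1, length(p)); non <- rep(1, length(p))
  i2 <- !is.na(genotypes) & genotypes == 2L
  i1 <- !is.na(genotypes) & genotypes == 1L
  i0 <- !is.na(genotypes) & genotypes == 0L
  hbd[i2] <- (1 - eps) * p[i2] + eps * p[i2]^2
  hbd[i1] <- eps * 2 * p[i1] * q[i1]
  hbd[i0] <- (1 - eps) * q[i0] + eps * q[i0]^2
  non[i2] <- p[i2]^2
  non[i1] <- 2 * p[i1] * q[i1]
  non[i0] <- q[i0]^2
  B <- cbind(matrix(hbd, nrow = length(p), ncol = model$n_states - 1L), non)
  B[B < 1e-300] <- 1e-300
  B
}

#' Inter-marker transition matrix
#'
#' Between two markers separated by d Morgans the current class-c segment
#' survives with probability exp(-R_c d); otherwise it terminates and a new
#' segment starts, drawn from the mixing distribution:
#' \deqn{A_{c,c'} = e^{-R_c d}\,1\{c = c'\} + (1 - e^{-R_c d})\, m_{c'}.}
#'
#' @param d inter-marker distance in Morgans, >= 0.
#' @param model an [hbd_model()].
#' @return A stochastic `n_states` x `n_states` matrix.
#' @export
transition_matrix <- function(d, model) {
  if (!is.numeric(d) || d < 0) stop("distance d must be non-negative")
  e <- exp(-model$rates * d)
  A <- diag(e) + (1 - e) %o% model$mixing
  dimnames(A) <- list(model$state_names, model$state_names)
  A
}
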