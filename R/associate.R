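# Per-component association screening: which principal components carry
# diagnosis signal, and which merely track nuisance factors (age, sex, head
# motion, imaging site, symptom score)?

#' Associate PCA scores with phenotype factors
#'
#' For every component and every requested factor, tests the component's
#' subject scores against the factor: a two-sample t-test for binary
#' factors (diagnosis, sex), Pearson correlation for continuous factors
#' (age, symptom score, mean FD; missing symptom scores are dropped
#' pairwise), and one-way ANOVA for imaging site. p-values are
#' BH-corrected WITHIN each factor across components.
#'
#' @param pc an [fit_pca()] model.
#' @param pheno phenotype table (see [check_phenotype()]).
#' @param factors phenotype columns to test; defaults to every supported
#'   column present.
#' @param q FDR level for the per-factor significance flags.
#' @param welch use Welch (unequal-variance) t-tests instead of pooled.
#' @return a data frame of class `pc_association` with columns
#'   `component`, `explained`, `factor`, `test`, `statistic`, `p`,
#'   `q_value`, `significant`.
#' @export
associate <- function(pc, pheno,
                      factors = intersect(c("diagnosis", "symptom_score",
                                            "age", "sex", "mean_fd",
                                            "site"),
                                          names(pheno)),
                      q = 0.05, welch = FALSE) {
  stopifnot(inherits(pc, "fc_pca"))
  pheno <- check_phenotype(pheno)
  if (nrow(pc$scores) != nrow(pheno)) {
    stop("pheno rows must match the subjects the PCA was fit on")
  }
  miss <- setdiff(factors, names(pheno))
  if (length(miss)) stop("factor column(s) absent: ",
                         paste(miss, collapse = ", "))
  k <- nrow(pc$weights)
  out <- lapply(factors, function(fac) {
    v <- pheno[[fac]]
    kind <- factor_test_kind(fac, v)
    res <- switch(kind,
      t = {
        f <- factor(v)
        if (nlevels(f) != 2) stop("binary factor '", fac,
                                  "' must have exactly 2 observed levels")
        vapply(seq_len(k), function(i) {
          tt <- stats::t.test(pc$scores[, i] ~ f, var.equal = !welch)
          c(tt$statistic, tt$p.value)
        }, numeric(2))
      },
      r = {
        if (stats::sd(v, na.rm = TRUE) == 0) {
          stop("continuous factor '", fac, "' is constant")
        }
        vapply(seq_len(k), function(i) {
          ok <- !is.na(v)
          ct <- stats::cor.test(pc$scores[ok, i], v[ok])
          c(ct$estimate, ct$p.value)
        }, numeric(2))
      },
      F = {
        f <- factor(v)
        small <- table(f) < 2
        if (any(small)) {
          stop("site(s) with < 2 subjects under ANOVA: ",
               paste(names(small)[small], collapse = ", "))
        }
        vapply(seq_len(k), function(i) {
          ow <- stats::oneway.test(pc$scores[, i] ~ f, var.equal = TRUE)
          c(ow$statistic, ow$p.value)
        }, numeric(2))
      })
    bh <- bh_fdr(res[2, ], q)
    data.frame(component = seq_len(k), explained = pc$explained,
               factor = fac,
               test = c(t = "two-sample t", r = "Pearson r",
                        F = "one-way ANOVA")[[kind]],
               statistic = res[1, ], p = res[2, ], q_value = bh$q_value,
               significant = bh$reject, row.names = NULL)
  })
  out <- do.call(rbind, out)
  attr(out, "q") <- q
  class(out) <- c("pc_association", "data.frame")
  out
}

factor_test_kind <- function(fac, v) {
  if (fac %in% c("diagnosis", "sex")) return("t")
  if (fac == "site") return("F")
  if (fac %in% c("age", "mean_fd", "symptom_score")) return("r")
  # fall back on the column's type for user-supplied factors
  if (is.numeric(v)) "r" else if (nlevels(factor(v)) == 2) "t" else "F"
}

#' Pick the diagnosis component
#'
#' Among components significantly associated with diagnosis (after BH
#' correction within the diagnosis factor), returns the one with the
#' largest explained variance. `NULL` -- a valid outcome -- means no
#' component carries detectable diagnosis signal and no features should be
#' selected. Explained-variance ties go to the lower component index (with
#' a message).
#'
#' @param assoc an [associate()] result containing the `diagnosis` factor.
#' @return a component index, or `NULL`.
#' @export
choose_diagnosis_pc <- function(assoc) {
  stopifnot(inherits(assoc, "pc_association"))
  dd <- assoc[assoc$factor == "diagnosis", ]
  if (nrow(dd) == 0) stop("association table has no 'diagnosis' factor")
  dd <- dd[dd$significant, ]
  if (nrow(dd) == 0) return(NULL)
  best <- dd$explained == max(dd$explained)
  if (sum(best) > 1) {
    message("explained-variance tie; choosing the lower component index")
  }
  min(dd$component[best])
}

#' @export
print.pc_association <- function(x, ...) {
  sig <- x[x$significant, c("component", "factor", "test", "statistic",
                            "q_value")]
  cat("<pc_association> ", length(unique(x$component)), " components x ",
      length(unique(x$factor)), " factors (q = ", attr(x, "q"), ")\n",
      sep = "")
  if (nrow(sig)) {
    cat("significant component-factor pairs:\n")
    print.data.frame(sig, row.names = FALSE, digits = 3)
  } else cat("no significant component-factor pairs\n")
  invisible(x)
}
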