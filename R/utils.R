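# internal helpers

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# matrix <-> EBImage orientation bridge (EBImage stores x in dim 1)
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

# restrict every instance of a label matrix to its largest 4-connected
# component (stray pixels fall back to background)
keep_largest_component <- function(lab) {
  for (i in sort(unique(lab[lab > 0L]))) {
    bin <- lab == i
    cc <- matrix(as.integer(from_ebi(EBImage::bwlabel(as_ebi(bin)))),
                 nrow(lab), ncol(lab))
    if (max(cc) > 1L) {
      sizes <- tabulate(cc[cc > 0L])
      lab[bin & cc != which.max(sizes)] <- 0L
    }
  }
  lab
}
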