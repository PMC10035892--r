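# Small deterministic fixtures shared across test files.

ryr_grid <- function() class_grid(matrix(c("R", "Y", "R"), nrow = 1))
ry_grid <- function() class_grid(matrix(c("R", "Y"), nrow = 1))

# a random grid possibly containing background, as an integer class_grid
random_grid <- function(h, w, p = c(0.2, 0.4, 0.4), seed = 1) {
  withr::with_seed(seed, {
    class_grid(matrix(sample(0:2, h * w, TRUE, prob = p), h, w))
  })
}

tau_of <- function(tab, from, to) tab$tau[tab$from == from & tab$to == to]

label_counts_of <- function(g) {
  tab <- tabulate(unclass(g) + 1L, nbins = 3L)
  c(empty = tab[1], red = tab[2], yellow = tab[3])
}
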