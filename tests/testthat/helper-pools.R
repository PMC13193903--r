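# Larger rendered pools for the acceptance-level property runs. Built once
# per session and cached; all seeds fixed.

# single breed x condition pool, n_per_class per class, bulls/ejaculates
# assigned cyclically
domain_pool <- function(domkey, n_per_class, seed0) {
  cached(paste("dp", domkey, n_per_class, seed0, sep = "_"), {
    doms <- default_domains()
    dom <- doms[[domkey]]
    labs <- rep(morph_classes(), each = n_per_class)
    imgs <- lapply(seq_along(labs), function(i)
      generate_cell(labs[i], dom, rng_seed = seed0 + i)$image)
    manifest <- data.frame(
      image_id = sprintf("p_%s_%05d", domkey, seq_along(labs)),
      bull_id = sprintf("%s_b%02d", domkey, (seq_along(labs) - 1) %% 3 + 1),
      breed = dom$breed, condition = dom$condition, season = dom$season,
      ejaculate_id = sprintf("%s_e%02d", domkey,
                             (seq_along(labs) - 1) %% 6 + 1),
      label = labs, stringsAsFactors = FALSE)
    structure(list(manifest = manifest, x = prepare_inputs(imgs)),
              class = "ifc_pool")
  })
}

# three-breed pool within one condition (for LOBO runs)
multi_breed_pool <- function(cond, n_per_class_breed, seed0) {
  cached(paste("mbp", cond, n_per_class_breed, seed0, sep = "_"), {
    doms <- default_domains()
    rows <- list()
    imgs <- list()
    i <- 0
    for (b in c("KW", "SIM", "AUL")) {
      dom <- doms[[paste0(b, ".", cond)]]
      for (cls in morph_classes()) for (r in seq_len(n_per_class_breed)) {
        i <- i + 1
        imgs[[i]] <- generate_cell(cls, dom, rng_seed = seed0 + i)$image
        rows[[i]] <- data.frame(
          image_id = sprintf("q%05d", i),
          bull_id = sprintf("%s_b%d", b, r %% 2 + 1), breed = b,
          condition = cond, season = dom$season,
          ejaculate_id = sprintf("%s_b%d_e%d", b, r %% 2 + 1, r %% 3 + 1),
          label = cls, stringsAsFactors = FALSE)
      }
    }
    structure(list(manifest = do.call(rbind, rows),
                   x = prepare_inputs(imgs)), class = "ifc_pool")
  })
}

pool_data <- function(pool, sub) {
  list(x = pool$x[match(sub$image_id, pool$manifest$image_id), ,
                  drop = FALSE],
       y = sub$label)
}
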