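# golgicode

Glycans displayed at the plasma membrane act as a molecular code of cell
identity. They are built by sequential enzymatic modification as proteins
transit the stack of Golgi cisternae, so the displayed glycan distribution
is shaped by a small set of physical parameters: the number of cisternae
`N_C`, the number of enzyme species `N_E`, their catalytic capacities and
placements, the inter-cisternal transfer rates, and how specifically each
enzyme recognizes its substrates. `golgicode` implements a quantitative
framework for asking how faithfully such a machinery can synthesize a
prescribed target distribution, and what trade-offs between cisternal
number, enzyme number and enzyme specificity that fidelity imposes. It is
aimed at systems biologists modelling secretory-pathway organization and at
anyone studying resource trade-offs in sequential biochemical synthesis.

## The model

Protein is injected into cisterna 1 at rate `q` and hops cisterna to
cisterna at rates `mu^(j)`; inside cisterna `j` the chain reaction
`k -> k+1` (glycan index `k = 1..N_s`) proceeds at the effective rate

    R_eff(j, k) = sum_a R_a^(j) * exp(-sigma * |k - l_a^(j)|),

where `l_a^(j)` is the ideal substrate shape of enzyme `a` and `sigma` its
specificity (`sigma = 0`: fully promiscuous; large `sigma`: lock-and-key).
Full Michaelis–Menten kinetics with enzyme sharing across substrates is
also implemented and reduces to the linear form in the dilute limit. The
displayed distribution is the normalized exit flux
`cbar_k = mu^(N_C) c_k^(N_C) / q`.

The fidelity of the machinery for a target `c*` is the normalized
Kullback–Leibler divergence

    F(c* || cbar) = D(c* || cbar) / H(c*)        (lower is better),

minimized over `(mu, R, L)` inside physiological boxes
(`mu` in `[0.01, 1]`/min, `R` in `[0.018, 20]`/min) by multi-start
box-constrained quasi-Newton search, with the specificity `sigma` scanned.
Around the package core sit: a Gaussian-mixture complexity estimator for
glycan profiles (weighted EM; the number of components at which the KL
curve saturates), a sigmoid-smoothed diversity objective, finite-difference
Hessian analysis of the fidelity landscape (stiff/sloppy directions,
degeneracies), and a synthetic-data generator for mixture-shaped targets
and MSMS-like noisy profiles.

## Worked example

```r
library(golgicode)

# a 3-peak target on 200 glycan indices (synthetic stand-in for a
# denoised MSMS profile)
target <- make_gmm_target(200, sample_gmm_components(200, 3, seed = 11))

# how many cisternae/enzymes, and how specific, to synthesize it?
sys <- golgi_system(NC = 3, NE = 3, Ns = 200)
scan <- scan_sigma(sys, target, c(0, 0.25, 0.5, 1), n_starts = 8, seed = 1,
                   control = list(maxit = 200), keep_fits = TRUE)
scan
#> # A tibble: 4 x 4
#>   sigma  Dbar fraction_near_best error
#>   <dbl> <dbl>              <dbl> <chr>
#> 1  0    0.526              1     <NA>
#> 2  0.25 0.161              0.125 <NA>
#> 3  0.5  7.72               1     <NA>
#> 4  1    7.72               1     <NA>
attr(scan, "sigma_min")
#> [1] 0.25
```

`Dbar` is the best fidelity found at each specificity: this machinery fits
the 3-peak target best with moderately promiscuous enzymes
(`sigma_min = 0.25`). At `sigma = 0` enzymes cannot shape peaks at all;
beyond the optimum the landscape fragments into local minima (the fraction
of starts near the best value collapses, then every start sticks at the
same poor value) and the fit degrades.

```r
fit <- attr(scan, "fits")[[which.min(scan$Dbar)]]
glance(fit)
#> # A tibble: 1 x 8
#>   objective sigma best_value n_starts fraction_near_best    NE    NC    Ns
#>   <chr>     <dbl>      <dbl>    <int>              <dbl> <int> <int> <int>
#> 1 fidelity   0.25      0.161        8              0.125     3     3   200

# stiff and sloppy directions at the optimum
ha <- hessian_at(sys, target, fit$best_params)
round(ha$group_stiffness, 3)
#>  sigma      L      R     mu
#> 10.042  4.312 -0.639 -3.623
tidy(ha)[1:3, ]
#> # A tibble: 3 x 3
#>    rank eigenvalue group
#>   <int>      <dbl> <chr>
#> 1     1     22972. sigma
#> 2     2       367. L
#> 3     3       154. L
```

The group stiffness (log mean Hessian eigenvalue per parameter block) says
the displayed code is by far most sensitive to the specificity `sigma`,
then to the enzyme placements `L`, and least to the transfer rates — the
cell must control specificity tightly, while rates can drift.

The complexity of a profile is read off the mixture KL curve:

```r
call_complexity(target, m_max = 6, restarts = 5, seed = 1)
#> <complexity_call> m* = 3
```

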