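---
title: "Delay-based reservoir computing: model, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-based reservoir computing: model, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayrc)
```

## The model

`delayrc` simulates the minimal reservoir-computing architecture in which a
whole recurrent network is replaced by **one** nonlinear node with delayed
self-feedback,

$$\dot x(t) = -x(t) + f\big(x(t-\tau),\, J(t)\big),$$

with all times in units of the node's characteristic time scale ($T \equiv 1$).
The reservoir's "nodes" are virtual: $N$ equidistant temporal positions
separated by $\theta = \tau/N$ along the delay line. A discrete input stream
$u(k)$ is sample-and-held over one mask span, multiplied slot-by-slot by a
length-$N$ mask $w$ and injected as the piecewise-constant drive
$J(t) = \gamma\, w_j\, u(k)$ on slot $j$. The state of virtual node $j$ at
step $k$ is the trajectory value at the end of its $\theta$-slot; collecting
them gives the $N \times K$ state matrix $S_M$, and a linear readout
$y_k = \sum_j \omega_{jk} x_j$ (ridge regression, optional intercept) maps
states to outputs.

The default nonlinearity is the Ikeda-type interference curve
$f(x, J) = \beta \sin^2(x + J + \phi)$: $\beta$ is the nonlinearity gain and
$\phi$ the offset phase that selects the operating point. At the autonomous
fixed point $x^\*$ the response has slope $\beta \sin 2(x^\*+\phi)$ (linear
response, hence memory) and curvature $2\beta \cos 2(x^\*+\phi)$
(nonlinearity, hence dimensional expansion); moving $\phi$ trades one for
the other, which is the axis explored by `sweep_phi()`. A saturating
Mackey-Glass-type family $f(x,J) = \beta z/(1+z^p)$, $z = x+J$, and a purely
linear family $f = \eta(x+J)$ are included; the Mackey-Glass form is the
standard saturating one, adopted because electronic implementations are
usually described only by the family name, and its exponent is exposed as
`mg_exponent`.

## Numerical integration

The delay equation is integrated on the grid $h = \theta/\rho$
(`oversampling` $\rho$, default 20). Because the delayed argument is always
at least one delay interval old, each interval reduces to a *linear*
recurrence $x_i = a\,x_{i-1} + \text{forcing}_i$ with precomputable forcing,
evaluated by `stats::filter()` at C speed. Two schemes are provided:
explicit Euler ($a = 1-h$, first order — the default, adequate because the
system is non-stiff at $T = 1$) and a Heun predictor–corrector with the
delayed term explicit ($a = 1-h+h^2/2$). The step-halving tests confirm the
expected convergence orders, and fixed points of the discrete map coincide
with those of the continuous system, so operating-point analyses are not
biased by $h$.

Initial history on $[-\tau, 0)$ defaults to zeros (a scalar or full vector
can be supplied); the first `warmup = 3` delay intervals of every run are
discarded, which the history-independence tests show is enough to make the
retained states insensitive to the arbitrary history in contractive
regimes. Trajectories exceeding $|x| > 10^6$ abort with the offending input
span named.

## Input layer

Masks come in four kinds: `binary_random` (±1), `binary_mls` (one period of
a maximum length sequence from a primitive LFSR, $N = 2^m - 1$, with the
classic flat circular autocorrelation $-1/N$), `multivalued` (default levels
$\{\pm 1, \pm 1/3\}$) and `analog` (smooth seeded noise). Two mask/delay
timings are supported. *Matched*: mask span $= \tau$, $\theta = \tau/N$;
virtual nodes couple through the node's inertia, which requires
$0.1 < \theta < 1$ (a warning is emitted outside this band).
*Desynchronized*: the delay is one slot longer than the mask span
($\theta = \tau/(N+1)$, span $= \tau - \theta$), so the mask start drifts by
one $\theta$ per delay interval and the drift itself provides the coupling.
The one-slot shortfall is the minimal choice that yields ring-like
connectivity; larger shortfalls would only permute the ring.

Vector-valued inputs (e.g. multi-channel feature frames) are supported by
concatenating the channels of each time step across the mask span: slot $j$
carries channel $\lceil jC/N \rceil$, keeping the mask length at $N$.

## Task-independent quality measures

**Linear memory capacity.** Per lag $i$, a readout is trained to reproduce
$u(k-i)$ from the states driven by i.i.d. uniform input on $[-1,1]$;
$m_i$ is the *squared* Pearson correlation between readout and delayed input
on a held-out 20 % split, and $\mu_c = \sum_i m_i$, truncated at
`horizon = 2N` with an early stop after five consecutive $m_i < 10^{-3}$.
The squared form is used because only it satisfies the ceiling
$\mu_c \le N$ that defines the measure; the raw coefficient would not. A
held-out split is used because in-sample correlations of a least-squares
readout are biased upward. All lag readouts share one SVD of the design
matrix, so the horizon is cheap.

**Kernel quality and generalization rank.** $N$ random probe inputs of
length $k = 20$ steps are run through the reservoir ($k-1$ steps of warmup);
the final state columns form an $N \times N$ matrix whose numerical rank is
$r_{kq}$. For the generalization rank $r_g$ the probes share their final
$l$ elements (default $l = k-1$), so a well-generalizing reservoir responds
nearly identically to all probes and $r_g$ collapses. The computational
ability is $r_c = r_{kq} - r_g$. Numerical rank counts singular values
$\ge 10^{-6}$ times the largest — analog states are never exactly dependent,
so this tolerance is the single most performance-sensitive choice and is
exposed everywhere the ranks are (including the CLI's `--rank-tolerance`).

**Detection noise.** Hardware readouts are dominated by detection and
quantization noise at the output layer, so `add_detection_noise()` perturbs
the *state matrix* with zero-mean Gaussian noise scaled to a target SNR in
dB; reservoir-internal noise is deliberately not modelled. The package
reproduces the qualitative asymmetry between tasks: one-step prediction
degrades sharply with falling SNR while winner-take-all classification is
comparatively resilient (misclassification only needs the output ranking to
survive).

## Synthetic benchmarks and what they do (not) show

All benchmarks are generated in code from a seed.

*NARMA-10* uses the standard tenth-order recurrence
$y(k{+}1) = 0.3 y(k) + 0.05 y(k)\sum_{i=0}^{9} y(k-i) + 1.5 u(k{-}9)u(k) + 0.1$
with $u \sim U[0, 0.5]$ (the benchmark is usually cited by name only; these
are its conventional coefficients). Under zero input the recurrence settles
at $y^\* = 0.7 - \sqrt{0.29} \approx 0.1615$, which the tests verify against
an independent fixed-point iteration.

*Chaotic one-step prediction* uses a Mackey-Glass delay recurrence in its
chaotic regime ($a{=}0.2$, $b{=}0.1$, delay 17, Euler step 0.1, subsampled by
10), standardized, as a generated stand-in for recorded laser-intensity
series. A persistence forecast is the built-in baseline.

*Pattern classification* is a miniature cochleagram task standing in for
isolated spoken-digit recognition: each of 10 classes is a fixed smooth
positive envelope over 16 channels × 20 steps; an item is its class envelope
modulating an item-specific random ±1 carrier, with ±10 % amplitude jitter
(speaker variability) and additive Gaussian noise (`noise_sd = 0.3`).
Because the carrier is zero-mean, *every linear functional of the input has
identical class means*: classification requires a nonlinear
(energy-detecting) transformation, exactly the property that makes the
curvature of the node response matter, while demanding little memory. An
earlier, simpler design (template plus additive noise) turned out to be
linearly separable and therefore could not distinguish linear from nonlinear
reservoirs at all — worth remembering when building classification
surrogates. What these generators do *not* emulate: real cochlear filter
banks, variable-duration utterances, nonstationary noise, or any
quantitative error level of hardware experiments; passing tests show the
architecture reproduces the *qualitative* dependence of performance on
operating point, reservoir size and SNR, not absolute published error rates.

## Default parameters and why

| parameter | default | why |
|---|---|---|
| $\rho$ (`oversampling`) | 20 | Euler error well below task noise; $\times 4$ runtime headroom |
| warmup | 3 delay intervals | history influence $\lesssim |f'|^3$; tests require $<10^{-6}$ leakage in contractive regimes |
| $\gamma$ (experiment layer) | 1 | drives the $\sin^2$ curve across a full quadrant for unit-scale inputs |
| mask (experiment layer) | `multivalued` | amplitude diversity: with a ±1 mask all nodes sample the same $|J|$, which caps classification performance regardless of $N$ |
| ridge $\lambda$ | $10^{-6}\,\overline{\mathrm{diag}(S S^{\top})}$ | scale-aware, negligible bias for regression |
| ridge $\lambda$ (classification) | $10^{-3}\,\overline{\mathrm{diag}(S S^{\top})}$ | one-hot targets on carrier-noise-dominated states; only the ranking matters |
| rank tolerance | $10^{-6}$ (relative) | separates genuine directions from integrator round-off |
| memory-capacity reservoir | linear, $\eta = 0.9$, $\theta = 1$ | $\theta$ at the top of the recommended band minimizes the inertia low-pass that degrades the conditioning of the linear map ($\mu_c \approx 19$ of 20 at $\theta=1$ vs. $\approx 12$ at $\theta=0.2$) |
| rank-protocol operating point | $\beta = 1.2$, $\phi = 0$, $\gamma = 1$ | strong gain and drive around the $\sin^2$ extremum: $r_{kq} \to N$ |
| NARMA operating point | $\beta = 0.9$, $\phi = \pi/4 - \beta/2$ | places the autonomous fixed point exactly at maximal slope ($f' = \beta$), the ~10-step memory the task needs; at slopes $\approx 0.6$ the lag-9 influence ($0.6^9$) is already too faint |

In size sweeps (`sweep_N()`) the node separation $\theta$ is held fixed and
the delay line grows with $N$ ($\tau = N\theta$): the node's bandwidth is a
physical property of the device, the delay line is the cheap resource.

Problem sizes used by the bundled end-to-end checks and the acceptance
script — $10^4$ samples for capacity, $N=50$ rank protocols, 2 400-step
NARMA runs at $N=400$, 9-point $\phi$ grids with 3–5 repeats, 200–300-item
classification sets — were chosen as the smallest sets at which the reported
quantities are stable to a few percent across seeds.

## Degenerate inputs, ties, and edge rules

Winner-take-all ties break toward the lowest class index. NMSE is undefined
for zero-variance targets (error, not NaN). The SNR of an all-zero state
matrix is undefined (error). A drive that does not span a whole number of
mask applications loses its partial final span with a warning. `binary_mls`
refuses lengths other than $2^m - 1$ rather than truncating a period, since
a truncated MLS loses the autocorrelation property that motivates it.

## Known limitations

Single delay loop only (no multi-delay memory shaping); no output feedback,
online learning or Boolean nodes; no hardware bandwidth modelling; the
Mackey-Glass family is a stand-in form, with exponent exposed but no claim
to match any specific electronic implementation; `consistency_check()`
flags, but does not map, inconsistent (e.g. chaotic) regimes.
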