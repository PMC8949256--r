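# Orthogonal wavelet decomposition low-pass filter coefficients (standard
# published tables, full double precision). High-pass and reconstruction
# filters are derived by the quadrature-mirror relations in wavelet_filters().
#
# db18/db19/db20: Daubechies extremal-phase; sym15: least-asymmetric
# (Symlet); dmey: 62-tap FIR approximation of the discrete Meyer wavelet.
# The dmey FIR filter is only near-orthogonal, so its analysis/synthesis
# round-trip is exact to ~1e-2, not machine precision (a property of the
# standard filter itself, identical in MATLAB and PyWavelets).
.wavelet_dec_lo <- list(
  dmey = c(
    0.00000000000000000e+00, -1.00999995694142294e-12, 8.51945963679621401e-09, -1.11194495259527797e-08,
    -1.07988195396219579e-08, 6.06697574135113522e-08, -1.08665165367358828e-07, 8.20068065038648134e-08,
    1.17830044976639342e-07, -5.50634056525227817e-07, 1.13079470179167064e-06, -1.48954921649715594e-06,
    7.36757288590374602e-07, 3.20544191334477983e-06, -1.63126997345528074e-05, 6.55430593057514913e-05,
    -6.01150234351609247e-04, -2.70467212464372501e-03, 2.20253410091100213e-03, 6.04581409732330398e-03,
    -6.38771831849715629e-03, -1.10614963925134511e-02, 1.52700151309348026e-02, 1.74234341037296930e-02,
    -3.21307939902117576e-02, -2.43487459060780231e-02, 6.37390243228015962e-02, 3.06550919608242628e-02,
    -1.32845200436229383e-01, -3.50875556562583457e-02, 4.44593002757577238e-01, 7.44585592318806277e-01,
    4.44593002757577238e-01, -3.50875556562583457e-02, -1.32845200436229383e-01, 3.06550919608242628e-02,
    6.37390243228015962e-02, -2.43487459060780231e-02, -3.21307939902117576e-02, 1.74234341037296930e-02,
    1.52700151309348026e-02, -1.10614963925134511e-02, -6.38771831849715629e-03, 6.04581409732330398e-03,
    2.20253410091100213e-03, -2.70467212464372501e-03, -6.01150234351609247e-04, 6.55430593057514913e-05,
    -1.63126997345528074e-05, 3.20544191334477983e-06, 7.36757288590374602e-07, -1.48954921649715594e-06,
    1.13079470179167064e-06, -5.50634056525227817e-07, 1.17830044976639342e-07, 8.20068065038648134e-08,
    -1.08665165367358828e-07, 6.06697574135113522e-08, -1.07988195396219579e-08, -1.11194495259527797e-08,
    8.51945963679621401e-09, -1.00999995694142294e-12),
  db18 = c(
    -2.50793445494859831e-09, 3.06883586304517494e-08, -1.17609876702823172e-07, -7.69163268988517661e-08,
    1.76871298362761550e-06, -3.33263447888582197e-06, -8.52060253744669594e-06, 3.74123788074003850e-05,
    -1.53591712353472464e-07, -1.98648552311747958e-04, 2.13581561910340700e-04, 6.28465682965145735e-04,
    -1.34059629833610658e-03, -1.11873266699249714e-03, 4.94334360546673773e-03, 1.18630033858117462e-04,
    -1.30514809466120013e-02, 6.26216795430570728e-03, 2.66707059264705906e-02, -2.37332103958600021e-02,
    -4.45261419029823260e-02, 5.70512477385368838e-02, 6.48872162119054491e-02, -1.06752246659828492e-01,
    -9.23318841508462829e-02, 1.67081312763257411e-01, 1.49533975565377786e-01, -2.16480934005142983e-01,
    -2.93654040736558763e-01, 1.47223111969928155e-01, 5.71801654888651312e-01, 5.71826807766607215e-01,
    3.14678941337031726e-01, 1.03588465822423592e-01, 1.92885317241463759e-02, 1.57631021844076053e-03),
  db19 = c(
    8.66684883899761893e-10, -1.11640206703582589e-08, 4.63693777578260454e-08, 1.44708829879784453e-08,
    -6.86275565776914270e-07, 1.53193147669119301e-06, 3.01096431629652654e-06, -1.66401762971549446e-05,
    5.10595048707388623e-06, 8.71127046721992292e-05, -1.24600791734158777e-04, -2.60676135678627996e-04,
    7.35802520505435221e-04, 3.41808653458595751e-04, -2.68755180070158212e-03, 7.68954359257548376e-04,
    7.04074736710524288e-03, -5.86692228101217458e-03, -1.39883886785351422e-02, 1.93755498891761274e-02,
    2.16237674095850485e-02, -4.56742262772309102e-02, -2.65012362501230413e-02, 8.69067555558122318e-02,
    2.75843506256286675e-02, -1.42785695038736588e-01, -3.35185419023028772e-02, 2.12349743306278482e-01,
    7.46522697081032638e-02, -2.85838631755826245e-01, -2.28091394215482635e-01, 2.60894952651038847e-01,
    6.01704549127537902e-01, 5.24436377464654879e-01, 2.64388431740896768e-01, 8.12781132654595562e-02,
    1.42810984507643970e-02, 1.10866976318171060e-03),
  db20 = c(
    -2.99883648961931942e-10, 4.05612705555183281e-09, -1.81484324829969604e-08, 2.01432202355051265e-10,
    2.63392422627000128e-07, -6.84707959700055740e-07, -1.01199401001888617e-06, 7.24124828767362047e-06,
    -4.37614386218399715e-06, -3.71058618339471284e-05, 6.77428082837773011e-05, 1.01532889736702909e-04,
    -3.85104748699217631e-04, -5.34975984399769483e-05, 1.39255961932313642e-03, -8.31562172822556929e-04,
    -3.58149425960962260e-03, 4.42054238704579078e-03, 6.72162730225945703e-03, -1.38105261371519201e-02,
    -8.78932492390156056e-03, 3.22942995307695796e-02, 5.87468181181182662e-03, -6.17228996246804579e-02,
    5.63224685730743559e-03, 1.02291719174442561e-01, -2.47168273386135853e-02, -1.55458750707267945e-01,
    3.98502464577712018e-02, 2.28291050819916325e-01, -1.67270883090770081e-02, -3.26786800434034963e-01,
    -1.39212088011483881e-01, 3.61502298739331041e-01, 6.10493238938593863e-01, 4.72696185310901684e-01,
    2.19942113551397034e-01, 6.34237804590815218e-02, 1.05493946249503989e-02, 7.79953613666846293e-04),
  sym15 = c(
    9.71241973796334781e-06, -7.35966679891946959e-06, -1.60661866374953426e-04, 5.51225478555866533e-05,
    1.07056721946239587e-03, -2.67316446471805680e-04, -3.59016544737264173e-03, 3.42345073635124102e-03,
    1.00799770879056692e-02, -1.94050114309344685e-02, -3.88767168768334934e-02, 2.19376427197539546e-02,
    4.07354796968106767e-02, -4.10826666353824796e-02, 1.11533695142618725e-01, 5.78640415215034509e-01,
    7.21843029636181188e-01, 2.43962705432166305e-01, -1.96626358766237297e-01, -1.34056298456253886e-01,
    6.83933100604802446e-02, 6.79698290448791792e-02, -8.74478888647795168e-03, -1.71712527816387309e-02,
    1.52613827818199829e-03, 3.48102873706489496e-03, -1.08154401685455251e-04, -4.02168537602934828e-04,
    2.17178901507789189e-05, 2.86607085253180806e-05)
)
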