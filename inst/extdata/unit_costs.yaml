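# Multi-country nominal unit costs (2017-2020 tariffs, local currency).
# Sources: national tariff systems for Germany (InEK), Portugal (SNS) and
# the UK (NHS national tariff); local hospital prices for Leiden.
# CPI indices default to the identity (supply real health-CPI indices to
# inflate nominal values to an analysis year). The GBP->EUR rate is the
# 2020 rate implied by the published aggregate expenditure table (1.167).
fx_gbp_to_eur: 1.167
countries:
  Ulm:
    currency: EUR
    cpi: {price_year: 100, target_year: 100}
    costs:
      gp: 59.45
      therapist: 59.45
      specialist_outside: 112.84
      specialist_hospital: 112.84
      blood: 94.77
      ultrasound: 92.67
      elastography: 100
      biopsy: 131.1
      mri: 470.38
      mpmri: 301
  Leiden:
    currency: EUR
    cpi: {price_year: 100, target_year: 100}
    costs:
      gp: 15.7
      therapist: 24.52
      specialist_outside: 69.8
      specialist_hospital: 69.8
      blood: 15.0
      ultrasound: 105.51
      elastography: 100
      biopsy: 732.85
      mri: 425.8
      mpmri: 301
  Coimbra:
    currency: EUR
    cpi: {price_year: 100, target_year: 100}
    costs:
      gp: 4.51
      therapist: 63
      specialist_outside: 16.71
      specialist_hospital: 16.71
      blood: 19.52
      ultrasound: 25.72
      biopsy: 85.6
      mri: 127.9
      mpmri: 301
  UK:
    currency: GBP
    cpi: {price_year: 100, target_year: 100}
    costs:
      gp: 132
      therapist: 45
      specialist_outside: 279
      specialist_hospital: 279
      blood: 5.03
      ultrasound: 9
      elastography: 49
      biopsy: 726
      mri: 130
      mpmri: 258
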