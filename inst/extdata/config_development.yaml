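screening:
  q_negative:
  - 917.0
  - 193.0
  semiq_negative:
  - 615.0
  - 495.0
  fn_given_semiq_negative:
  - 36.0
  - 579.0
  tp_given_semiq_positive:
  - 157.0
  - 338.0
outcomes:
  ESRD:
    rate: 0.0006
    hr: 3.432
    hr_low: 2.757
    hr_high: 4.271
    unit_cost: 6810.38
  CVD:
    rate: 0.0154
    hr: 1.315
    hr_low: 1.25
    hr_high: 1.384
    unit_cost: 13149.62
  death:
    rate: 0.0095
    hr: 1.48
    hr_low: 1.408
    hr_high: 1.556
    unit_cost: 25634.48
cost_quant_test: 17.76
cost_semiq_test: 0.86
cost_transport: 9.265
transport_trips_quant: 2
transport_trips_semiq: 1
transport_trips_confirm: 1
discount_rate: 0.03
horizon: 10
cycle_length: 1.0
currency: USD, 2016 prices (1 USD = 1,160 KRW)
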