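county_id,latitude,weight,registry_id
C01,30.21,0.0128,R01
C02,30.85,0.02048,R02
C03,31.4,0.00768,R03
C04,31.92,0.03072,R04
C05,32.38,0.01792,R05
C06,32.77,0.0256,R06
C07,33.1,0.01024,R07
C08,33.48,0.02304,R08
C09,33.76,0.01536,R01
C10,34.02,0.02816,R02
C11,34.19,0.020533,R03
C12,34.6,0.032853,R04
C13,35.05,0.01232,R05
C14,35.52,0.04928,R06
C15,35.98,0.028747,R07
C16,36.41,0.041067,R08
C17,36.8,0.016427,R01
C18,37.12,0.03696,R02
C19,37.49,0.02464,R03
C20,37.86,0.045173,R04
C21,38.05,0.016333,R05
C22,38.47,0.026133,R06
C23,38.92,0.0098,R07
C24,39.35,0.0392,R08
C25,39.78,0.022867,R01
C26,40.16,0.032667,R02
C27,40.55,0.013067,R03
C28,40.9,0.0294,R04
C29,41.22,0.0196,R05
C30,41.51,0.035933,R06
C31,41.68,0.017,R07
C32,42.15,0.0272,R08
C33,42.7,0.0102,R01
C34,43.28,0.0408,R02
C35,43.85,0.0238,R03
C36,44.47,0.034,R04
C37,45.1,0.0136,R05
C38,45.78,0.0306,R06
C39,46.52,0.0204,R07
C40,47.31,0.0374,R08
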