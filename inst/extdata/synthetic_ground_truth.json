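[{"population_id":"pop01","sex":"female","mu":5.58826835313812,"sigma":7.03004158824775,"kappa":0.631885977439143,"theta":8.84379231801567},{"population_id":"pop01","sex":"male","mu":11.7098827369045,"sigma":13.7122726849152,"kappa":0.729266409041153,"theta":16.0570713140357},{"population_id":"pop02","sex":"female","mu":7.95235465094447,"sigma":10.0040621508881,"kappa":0.631885977439143,"theta":12.5851101858173},{"population_id":"pop02","sex":"male","mu":29.8520991636906,"sigma":34.9568081206817,"kappa":0.729266409041153,"theta":40.9344223093182},{"population_id":"pop03","sex":"female","mu":11.9798387307674,"sigma":15.0706371233054,"kappa":0.631885977439143,"theta":18.9588615011181},{"population_id":"pop03","sex":"male","mu":32.4255076772533,"sigma":37.9702694900637,"kappa":0.729266409041153,"theta":44.4631855728645}]
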