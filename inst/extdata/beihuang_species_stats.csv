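label,species,family,order,quantity,mass_min,mass_max,mass_mean,mass_sd,wingbeat_frequency_min,wingbeat_frequency_max,wingbeat_frequency_mean,wingbeat_frequency_sd,length_to_width_ratio_min,length_to_width_ratio_max,length_to_width_ratio_mean,length_to_width_ratio_sd,body_length_min,body_length_max,body_length_mean,body_length_sd,mass_range_suspect
A,Eriopyga grandis,Noctuidae,Lepidoptera,473,55.7,69.3,62.98,2.41,36,57,45.15,3.57,2,7,3.52,0.91,8,14,11.22,1.12,FALSE
B,Agrotis tokionis,Noctuidae,Lepidoptera,382,252.2,280.9,266.45,4.97,38,75,58.30,5.85,2.7,5.8,3.88,0.51,24,31,27.18,1.35,FALSE
C,Agrotis c-nigrum,Noctuidae,Lepidoptera,43,203.2,224.7,215.01,5.38,36,57,46.44,5.41,3.3,5.4,4.53,0.57,21,27,24.47,1.47,FALSE
D,Agrotis praecox,Noctuidae,Lepidoptera,78,209.9,253.3,233.83,7.86,31,58,42.47,5.38,3.2,5.2,4.00,0.46,18,27,22.70,1.83,FALSE
E,Spodoptera litura,Noctuidae,Lepidoptera,129,37.1,152.0,143.97,2.59,45,66,56.88,3.98,3,7,4.93,0.80,15,21,18.64,1.35,TRUE
F,Heliothis dipsacea,Noctuidae,Lepidoptera,84,100.6,114.4,107.37,2.72,37,56,44.31,3.48,3.2,8.0,4.44,0.84,13,19,15.51,1.26,FALSE
G,Speiredonia retorta,Noctuidae,Lepidoptera,32,306.1,355.6,326.96,10.63,18,30,24.75,3.02,4.4,9.3,6.72,1.32,22,29,25.47,1.88,FALSE
H,Dermaleipa juno,Noctuidae,Lepidoptera,61,444.5,511.8,472.79,13.09,22,34,28.34,2.48,3.0,4.5,3.71,0.30,39,45,42.56,1.47,FALSE
I,Acronicta rumicis,Noctuidae,Lepidoptera,58,76.7,91.8,85.35,4.18,41,57,48.76,3.92,4.0,7.5,4.99,0.56,12,16,14.72,0.87,FALSE
J,Calospilos suspecta,Geometridae,Lepidoptera,147,110.9,127.8,117.43,3.04,19,33,25.97,2.84,5.6,11,9.31,0.87,16,22,18.78,1.39,FALSE
K,Spilarctia subcarnea,Arctiidae,Lepidoptera,296,85.6,104.7,94.60,3.54,33,64,47.78,5.10,2.8,8.9,4.30,0.82,15,21,18.10,1.11,FALSE
L,Spilosoma niveus,Arctiidae,Lepidoptera,48,178.3,198.3,188.20,4.35,42,66,52.94,4.19,4.0,7.2,5.07,0.61,24,29,27.38,1.20,FALSE
M,Amsacta lactinea,Arctiidae,Lepidoptera,27,169.0,242.7,218.71,17.49,50,63,57.00,2.95,4,6,4.76,0.51,22,28,24.81,1.18,FALSE
N,Rhyparioides amurensis,Arctiidae,Lepidoptera,144,125.0,145.2,134.30,3.68,39,53,46.27,2.95,3.4,6.7,4.49,0.63,14,20,16.77,1.20,FALSE
O,Clanis bilineata,Sphingidae,Lepidoptera,53,416.0,519.0,459.28,23.32,31,40,36.51,1.76,2.6,5.8,3.56,0.62,38,47,42.98,2.18,FALSE
P,Psilogramma menephron,Sphingidae,Lepidoptera,29,311.4,337.5,326.18,5.82,38,45,41.48,1.62,4.5,6.7,5.43,0.49,41,48,46.00,1.87,FALSE
Q,Ampelophaga rubiginosa,Sphingidae,Lepidoptera,41,365.2,412.6,381.99,8.60,44,54,48.46,1.95,4.4,6.9,5.10,0.46,43,49,46.85,1.37,FALSE
R,Callambulyx tartarunovii,Sphingidae,Lepidoptera,35,277.0,332.7,304.78,13.68,42,50,45.60,1.93,2.0,2.6,2.26,0.17,28,34,31.29,1.34,FALSE
S,Macroglossum stellatarum,Sphingidae,Lepidoptera,84,211.7,244.1,227.29,7.00,182,289,233.40,19.60,1.8,2.9,2.25,0.19,24,31,27.77,1.47,FALSE
T,Loxostege sticticalis,Pyralididae,Lepidoptera,89,259.9,75.3,67.37,2.39,33,60,47.21,4.35,3.0,11,7.11,2.19,6,11,8.71,0.66,TRUE
U,Spoladea recurvalis,Pyralididae,Lepidoptera,157,45.2,23.8,14.52,2.79,28,59,42.28,4.88,2.5,8.0,6.14,0.71,4,8,6.19,0.58,TRUE
V,Pantala flavescens,Libellulidae,Odonata,768,138.8,223.0,182.77,13.07,120,155,137.48,5.70,4.4,6.5,5.40,0.37,60,74,66.64,2.26,FALSE
W,Enallagma cyathigerum,Coenagriidae,Odonata,54,121.1,130.1,125.15,2.05,74,92,82.76,3.87,7.3,13,9.04,1.07,42,53,47.19,1.91,FALSE
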