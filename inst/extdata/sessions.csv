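dyad_id,pretalk,intervention,posttalk,session_min,intervention_desc,diagnosis
P018,00:03:03,00:29:45,00:13:28,52.92,"Active music making (drums) and receptive music (patient shared music)",M54.5
P019,00:08:51,00:29:08,00:08:24,48.68,"Guided relaxation (sound bowls), song writing and performance",I63.5
P025,00:05:38,00:26:03,00:04:00,40.13,"Breath and voice work; singing and active music playing (patient on drums, therapist on ukulele)",M51.1
P028,00:07:46,00:23:59,00:06:46,54.67,"Deep listening exercise (sound bowls) and improvisation on the theme 'discovery' on harps",M54.4
P031,00:04:45,00:35:01,00:02:58,47.52,"Improvisation on theme 'holidays' (patient on chimes, therapist on harp) and active music making (drums)",M51.1
P032,00:24:40,00:11:29,00:05:50,53.97,"Vocal improvisation (therapist on voice and harp)",M51.1
P035,00:04:16,00:20:09,00:07:45,44.93,"Improvisation on theme 'under the stars' (harps) and free improvisation (harps and voices)",I63.9
P037,00:12:59,00:15:07,00:13:39,49.27,"Improvisation 'hands separated and together' (patient on chimes, therapist on harp)",M51.1
P047,00:04:44,00:34:32,00:06:28,52.15,"Deep listening (sound bowls), voice work and improvisation (harps)",M51.1
P048,00:17:48,00:27:52,00:13:00,62.48,"Improvisation on theme 'taking time' (patient on sansula, therapist on harp) and improvisation (patient with spoken words, therapist on sansula)",M51.1
P057,00:12:46,00:28:14,00:09:54,55.32,"Receptive music (patient's choice) and singing (songs from patient's native country)",M50.0
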