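factor,n_items,lead_item,n,r_factor,r_lead,low_power_factor,low_power_lead
Altruism,9,Think of others first.,15597,0.05,0.06,FALSE,FALSE
Anger,8,Lose my temper.,7056,0.10,0.11,FALSE,FALSE
Obedience,8,Try to follow the rules.,13777,0.07,0.08,FALSE,FALSE
Talkativeness,8,Have an intense boisterous laugh.,7883,0.08,0.15,FALSE,FALSE
Immoderation,6,Am able to control my cravings.,5572,-0.18,-0.21,FALSE,FALSE
Worry,6,Panic easily.,4386,0.07,0.08,FALSE,FALSE
Activity,5,Feel healthy and vibrant most of the time.,4107,-0.15,-0.16,FALSE,FALSE
Conventionality,5,See myself as an average person.,2762,0.10,0.11,FALSE,FALSE
Disorganization,5,Leave a mess in my room.,2536,0.14,0.16,FALSE,FALSE
Liveliness,5,Am rather lively.,3156,-0.09,-0.11,FALSE,FALSE
Mood swings,5,Get overwhelmed by emotions.,2284,0.03,0.04,TRUE,TRUE
Adventure-seeking,4,Seek adventure.,2032,-0.05,-0.06,TRUE,TRUE
Impulsivity,4,Dont know why I do some of the things I do.,1251,0.04,0.07,TRUE,TRUE
Preference for the familiar,4,Prefer to stick with things that I know.,2428,0.07,0.07,FALSE,FALSE
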